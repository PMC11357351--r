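#' Segment Golgi and plasma-membrane compartments from marker channels
#'
#' Thresholds the Golgi marker (GalT-RFP) and the plasma-membrane stain
#' (WGA) independently, removes pixels that pass both raw thresholds from
#' BOTH compartments (no pixel is double-counted), then cleans each mask by
#' minimum area. Hole filling is off by default: filling a membrane ring
#' would swallow the cell interior.
#'
#' @param field Field containing `GOLGI_RFP` and `PM_WGA` channels.
#' @param golgi_threshold,membrane_threshold Manual intensity thresholds;
#'   `NULL` (default) uses [otsu_mask()].
#' @param golgi_min_area,membrane_min_area Minimum component areas (px).
#' @param connectivity Component connectivity, 4 or 8.
#' @return List of class `compartment_masks`: logical `golgi` and
#'   `membrane` masks (guaranteed disjoint), pixel counts, thresholds used.
#' @export
segment_compartments <- function(field,
                                 golgi_threshold = NULL,
                                 membrane_threshold = NULL,
                                 golgi_min_area = 10L,
                                 membrane_min_area = 10L,
                                 connectivity = 8L) {
  g_raw <- threshold_channel(field_channel(field, "GOLGI_RFP"), golgi_threshold)
  m_raw <- threshold_channel(field_channel(field, "PM_WGA"), membrane_threshold)
  overlap <- g_raw & m_raw
  g_raw[overlap] <- FALSE
  m_raw[overlap] <- FALSE
  golgi <- clean_and_label(g_raw, min_area_px = golgi_min_area,
                           connectivity = connectivity) > 0L
  membrane <- clean_and_label(m_raw, min_area_px = membrane_min_area,
                              connectivity = connectivity) > 0L
  if (!any(golgi)) {
    stop_myoquant("Golgi marker (GOLGI_RFP) segmentation produced an empty mask.",
                  "myoquant_empty_compartment")
  }
  if (!any(membrane)) {
    stop_myoquant("membrane marker (PM_WGA) segmentation produced an empty mask.",
                  "myoquant_empty_compartment")
  }
  structure(list(golgi = golgi,
                 membrane = membrane,
                 n_golgi_px = sum(golgi),
                 n_membrane_px = sum(membrane),
                 golgi_threshold = attr_or(golgi_threshold, g_raw),
                 membrane_threshold = attr_or(membrane_threshold, m_raw)),
            class = "compartment_masks")
}

threshold_channel <- function(raster, threshold) {
  if (is.null(threshold)) otsu_mask(raster) else raster > threshold
}

attr_or <- function(manual, mask) {
  if (!is.null(manual)) manual else attr(mask, "threshold")
}

#' Golgi-to-membrane mean-intensity ratio of the HRas channel
#'
#' The per-field localization statistic: the arithmetic mean of the HRas
#' channel over the Golgi mask divided by its mean over the plasma-membrane
#' mask. Values below 1 indicate relative depletion at the Golgi.
#'
#' @param field Field containing `HRAS_EGFP`.
#' @param masks A `compartment_masks` object (or a list with logical
#'   `golgi` and `membrane` elements, e.g. generator ground truth).
#' @param field_id Identifier carried into the result row.
#' @return One-row tibble: `field_id`, `mean_golgi`, `mean_membrane`,
#'   `r_mean`, `n_golgi_px`, `n_membrane_px`, `undefined` (TRUE when the
#'   membrane mean is zero and the ratio cannot be formed).
#' @examples
#' hras <- matrix(120, 16, 16); hras[4:6, 4:6] <- 60
#' f <- new_field(list(HRAS_EGFP = hras))
#' golgi <- matrix(FALSE, 16, 16); golgi[4:6, 4:6] <- TRUE
#' membrane <- matrix(FALSE, 16, 16); membrane[12:14, ] <- TRUE
#' compute_rmean(f, list(golgi = golgi, membrane = membrane))$r_mean  # 0.5
#' @export
compute_rmean <- function(field, masks, field_id = NA_character_) {
  golgi <- masks$golgi
  membrane <- masks$membrane
  stopifnot(is.logical(golgi), is.logical(membrane))
  if (any(golgi & membrane)) {
    stop_myoquant("golgi and membrane masks must be disjoint.",
                  "myoquant_config_error")
  }
  hras <- field_channel(field, "HRAS_EGFP")
  if (!identical(dim(hras), dim(golgi))) {
    stop_myoquant("mask shape does not match the field.",
                  "myoquant_dimension_error")
  }
  mg <- mean(hras[golgi])
  mm <- mean(hras[membrane])
  undefined <- !is.finite(mm) || mm == 0
  tibble(field_id = field_id,
         mean_golgi = mg,
         mean_membrane = mm,
         r_mean = if (undefined) NA_real_ else mg / mm,
         n_golgi_px = sum(golgi),
         n_membrane_px = sum(membrane),
         undefined = undefined)
}

#' Batch localization analysis across conditions
#'
#' Segments and measures every field, then summarises the per-field ratios
#' by condition: mean, SD, percent change versus the control condition, and
#' a two-tailed Student t-test against the control. Fields whose
#' segmentation fails are excluded and reported.
#'
#' @param fields List of fields (optionally named; names become field ids).
#' @param conditions Character vector, one condition per field.
#' @param control Name of the control condition (default: first condition).
#' @param masks Optional list of precomputed masks per field (e.g.
#'   generator ground truth); `NULL` segments each field with
#'   [segment_compartments()].
#' @param ... Passed to [segment_compartments()].
#' @return Object of class `rmean_batch`: list with `per_field` tibble,
#'   `summary` tibble (`condition`, `n`, `mean_r`, `sd_r`, `pct_change`,
#'   `p_value`), and `excluded` tibble of failed fields.
#' @export
batch_rmean <- function(fields, conditions, control = NULL, masks = NULL, ...) {
  stopifnot(length(fields) == length(conditions), length(fields) >= 1L)
  ids <- names(fields)
  if (is.null(ids)) ids <- sprintf("field_%03d", seq_along(fields))
  if (is.null(control)) control <- conditions[[1L]]
  if (!control %in% conditions) {
    stop_myoquant(sprintf("control condition '%s' not present.", control),
                  "myoquant_config_error")
  }
  rows <- vector("list", length(fields))
  excluded <- list()
  for (i in seq_along(fields)) {
    res <- tryCatch({
      mk <- if (is.null(masks)) segment_compartments(fields[[i]], ...) else masks[[i]]
      compute_rmean(fields[[i]], mk, field_id = ids[[i]])
    }, myoquant_error = function(e) e)
    if (inherits(res, "error")) {
      warn(sprintf("field '%s' excluded: %s", ids[[i]], conditionMessage(res)))
      excluded[[length(excluded) + 1L]] <-
        tibble(field_id = ids[[i]], condition = conditions[[i]],
               reason = conditionMessage(res))
    } else {
      res$condition <- conditions[[i]]
      rows[[i]] <- res
    }
  }
  per_field <- bind_rows(rows) %>%
    select("field_id", "condition", dplyr::everything())
  summary <- per_field %>%
    filter(!.data$undefined) %>%
    group_by(.data$condition) %>%
    summarise(n = dplyr::n(), mean_r = mean(.data$r_mean),
              sd_r = sd(.data$r_mean), .groups = "drop")
  ctrl_vals <- per_field$r_mean[per_field$condition == control &
                                  !per_field$undefined]
  summary <- summary %>%
    mutate(
      pct_change = 100 * (.data$mean_r - mean(ctrl_vals)) / mean(ctrl_vals),
      p_value = purrr::map_dbl(.data$condition, function(cond) {
        if (cond == control) return(NA_real_)
        vals <- per_field$r_mean[per_field$condition == cond &
                                   !per_field$undefined]
        if (length(vals) < 2L || length(ctrl_vals) < 2L) return(NA_real_)
        ttest_two_tailed(vals, ctrl_vals)$p
      })
    )
  structure(list(per_field = per_field, summary = summary,
                 excluded = bind_rows(excluded), control = control),
            class = "rmean_batch")
}

#' @export
print.rmean_batch <- function(x, ...) {
  cat(sprintf("<rmean_batch> %d field(s), control = '%s'\n",
              nrow(x$per_field), x$control))
  print(x$summary)
  if (nrow(x$excluded)) {
    cat(sprintf("%d field(s) excluded.\n", nrow(x$excluded)))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.rmean_batch <- function(x, ...) x$per_field

#' @export
glance.rmean_batch <- function(x, ...) x$summary

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-field localization ratios by condition
#'
#' @param object An `rmean_batch`.
#' @param ... Unused.
#' @return A ggplot: per-field `r_mean` points with condition means.
#' @export
autoplot.rmean_batch <- function(object, ...) {
  ggplot2::ggplot(object$per_field,
                  ggplot2::aes(x = .data$condition, y = .data$r_mean)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "firebrick", linewidth = 0.4) +
    ggplot2::labs(x = NULL,
                  y = expression(R[mean] ~ "(Golgi / plasma membrane)")) +
    ggplot2::theme_minimal()
}
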
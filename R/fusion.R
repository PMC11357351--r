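#' Segment nuclei from the DAPI channel
#'
#' Otsu threshold, hole filling, minimum-area cleanup, then (optionally) a
#' distance-transform watershed to separate touching nuclei. A field with
#' no detectable nuclei returns an empty set with a warning rather than an
#' error: a field may truly be empty.
#'
#' @param field Field containing `DAPI`.
#' @param min_area Minimum nucleus area (px, default 30).
#' @param split_touching Run the watershed split.
#' @param watershed_tolerance Minimum height of an object's highest point
#'   above its merge level for it to count as a separate seed (the minimum
#'   seed separation knob of the split).
#' @return List of class `nuclei_set`: `labels` matrix, tibble `nuclei`
#'   (`label`, `area_px`, `centroid_row`, `centroid_col`, and `area_um2`
#'   when the field has a pixel size), and `n`.
#' @export
segment_nuclei <- function(field, min_area = 30L, split_touching = FALSE,
                           watershed_tolerance = 1) {
  dapi <- field_channel(field, "DAPI")
  mask <- tryCatch(otsu_mask(dapi), myoquant_degenerate_input = function(e) {
    matrix(FALSE, nrow(dapi), ncol(dapi))
  })
  labels <- clean_and_label(mask, min_area_px = min_area, fill_holes = TRUE)
  if (split_touching && attr(labels, "n_labels") > 0L) {
    bin <- labels > 0L
    dm <- EBImage::distmap(bin * 1L)
    ws <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1L)
    labels <- relabel_contiguous(matrix(as.integer(ws), nrow(bin), ncol(bin)))
    # watershed can carve sub-minimum fragments at boundaries; re-apply floor
    if (attr(labels, "n_labels") > 0L) {
      areas <- tabulate(labels[labels > 0L], nbins = attr(labels, "n_labels"))
      drop <- which(areas < min_area)
      if (length(drop)) {
        labels[labels %in% drop] <- 0L
        labels <- relabel_contiguous(labels)
      }
    }
  }
  nuclei <- label_stats(labels)
  if (!is.null(field$pixel_size_um)) {
    nuclei$area_um2 <- nuclei$area_px * field$pixel_size_um^2
  }
  if (nrow(nuclei) == 0L) {
    warn("no nuclei detected in this field.")
  }
  structure(list(labels = labels, nuclei = nuclei, n = nrow(nuclei),
                 pixel_size_um = field$pixel_size_um),
            class = "nuclei_set")
}

#' @export
print.nuclei_set <- function(x, ...) {
  cat(sprintf("<nuclei_set> %d nuclei\n", x$n))
  invisible(x)
}

#' Segment MHC-positive fibers
#'
#' Otsu threshold on the MHC immunostain followed by minimum-area cleanup;
#' each connected component is one fiber. A channel too uniform to
#' threshold yields zero fibers with a warning.
#'
#' @param field Field containing `MHC`.
#' @param min_area Minimum fiber area (px).
#' @return Integer label matrix (attribute `"n_labels"` = fiber count).
#' @export
segment_fibers <- function(field, min_area = 200L) {
  mhc <- field_channel(field, "MHC")
  mask <- tryCatch(otsu_mask(mhc), myoquant_degenerate_input = function(e) {
    warn("MHC channel is uniform; reporting zero fibers.")
    matrix(FALSE, nrow(mhc), ncol(mhc))
  })
  clean_and_label(mask, min_area_px = min_area)
}

#' Myotube fusion index
#'
#' Percentage of nuclei lying on MHC-positive fibers: a nucleus counts as
#' fused when the pixel under its centroid carries a positive fiber label
#' (default), or when at least half of its body overlaps a fiber
#' (`rule = "overlap50"`). A nucleus whose centroid falls on background but
#' whose rim touches a fiber is NOT fused under the default rule.
#'
#' @param nuclei A [segment_nuclei()] result.
#' @param fibers Fiber label matrix from [segment_fibers()] (or any integer
#'   label matrix of the same shape).
#' @param rule `"centroid"` or `"overlap50"`.
#' @return List of class `fusion_result`: one-row `summary` tibble
#'   (`n_total`, `n_in_fiber`, `fusion_index_pct`, `undefined`) and a
#'   `per_fiber` tibble (`fiber`, `n_nuclei`). `fusion_index_pct` is `NA`
#'   with `undefined = TRUE` when the field holds no nuclei.
#' @export
fusion_index <- function(nuclei, fibers, rule = c("centroid", "overlap50")) {
  rule <- match.arg(rule)
  stopifnot(inherits(nuclei, "nuclei_set"),
            identical(dim(nuclei$labels), dim(fibers)))
  n_total <- nuclei$n
  if (n_total == 0L) {
    return(structure(list(
      summary = tibble(n_total = 0L, n_in_fiber = 0L,
                       fusion_index_pct = NA_real_, undefined = TRUE),
      per_fiber = tibble(fiber = integer(), n_nuclei = integer())),
      class = "fusion_result"))
  }
  assigned <- if (rule == "centroid") {
    r <- pmin(pmax(round(nuclei$nuclei$centroid_row), 1L), nrow(fibers))
    c_ <- pmin(pmax(round(nuclei$nuclei$centroid_col), 1L), ncol(fibers))
    fibers[cbind(r, c_)]
  } else {
    vapply(nuclei$nuclei$label, function(lb) {
      under <- fibers[nuclei$labels == lb]
      if (mean(under > 0L) >= 0.5) {
        pos <- under[under > 0L]
        as.integer(names(which.max(table(pos))))
      } else 0L
    }, integer(1L))
  }
  fused <- assigned > 0L
  per_fiber <- tibble(fiber = assigned[fused]) %>%
    dplyr::count(.data$fiber, name = "n_nuclei") %>%
    arrange(.data$fiber)
  structure(list(
    summary = tibble(n_total = n_total,
                     n_in_fiber = sum(fused),
                     fusion_index_pct = 100 * sum(fused) / n_total,
                     undefined = FALSE),
    per_fiber = per_fiber,
    assigned = assigned),
    class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<fusion_result> %d / %d nuclei in fibers (%.1f%%)\n",
              s$n_in_fiber, s$n_total,
              ifelse(s$undefined, NA, s$fusion_index_pct)))
  invisible(x)
}

#' @export
tidy.fusion_result <- function(x, ...) x$per_fiber

#' @export
glance.fusion_result <- function(x, ...) x$summary

#' Nuclear-area statistics (senescence readout)
#'
#' Senescent myoblasts enlarge their nuclei; this summarises per-nucleus
#' areas, in square micrometres when a pixel size is available and in
#' pixels otherwise.
#'
#' @param nuclei A [segment_nuclei()] result.
#' @param pixel_size_um Physical pixel size; defaults to the one stored in
#'   the nuclei set (may be `NULL` for pixel units).
#' @return List: `per_nucleus` tibble and one-row `summary` tibble
#'   (`n`, `mean_area`, `median_area`, `sd_area`, `unit`).
#' @export
nuclear_area_stats <- function(nuclei, pixel_size_um = NULL) {
  stopifnot(inherits(nuclei, "nuclei_set"))
  if (is.null(pixel_size_um)) pixel_size_um <- nuclei$pixel_size_um
  per <- nuclei$nuclei
  if (nrow(per) == 0L) {
    return(list(per_nucleus = per,
                summary = tibble(n = 0L, mean_area = NA_real_,
                                 median_area = NA_real_, sd_area = NA_real_,
                                 unit = NA_character_)))
  }
  if (!is.null(pixel_size_um)) {
    stopifnot(pixel_size_um > 0)
    per$area_um2 <- per$area_px * pixel_size_um^2
    areas <- per$area_um2
    unit <- "um2"
  } else {
    areas <- per$area_px
    unit <- "px"
  }
  list(per_nucleus = per,
       summary = tibble(n = nrow(per), mean_area = mean(areas),
                        median_area = median(areas), sd_area = sd(areas),
                        unit = unit))
}
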
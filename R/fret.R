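#' Estimate bleed-through coefficients from single-label controls
#'
#' Cells expressing only the donor (EGFP) leak a fraction `a` of donor
#' signal into the transfer channel; cells expressing only the acceptor
#' (mCherry) contribute a fraction `b` through direct excitation. Each
#' coefficient is the slope of a least-squares regression through the
#' origin of the transfer-channel intensity on the single-label channel,
#' pooled over all calibration pixels above an intensity floor.
#'
#' @param donor_only List of fields with `DONOR` and `FRET` channels.
#' @param acceptor_only List of fields with `ACCEPTOR` and `FRET` channels.
#' @param floor_frac Intensity floor as a fraction of the pooled maximum of
#'   the single-label channel; pixels below it are excluded.
#' @param min_px Minimum pooled pixel count required per fit.
#' @return List of class `bleedthrough`: slopes `a` and `b`, pixel counts,
#'   residual sums of squares, and `out_of_bounds` flag set when a fitted
#'   slope falls outside `[0, 1)`.
#' @export
estimate_bleedthrough <- function(donor_only, acceptor_only,
                                  floor_frac = 0.1, min_px = 100L) {
  fit_a <- fit_origin_slope(donor_only, "DONOR", floor_frac, min_px, "donor-only")
  fit_b <- fit_origin_slope(acceptor_only, "ACCEPTOR", floor_frac, min_px,
                            "acceptor-only")
  coeffs <- structure(list(a = fit_a$slope, b = fit_b$slope,
                           n_px_donor = fit_a$n, n_px_acceptor = fit_b$n,
                           rss_donor = fit_a$rss, rss_acceptor = fit_b$rss,
                           out_of_bounds = FALSE),
                      class = "bleedthrough")
  if (coeffs$a < 0 || coeffs$a >= 1 || coeffs$b < 0 || coeffs$b >= 1) {
    coeffs$out_of_bounds <- TRUE
    warn(sprintf("bleed-through fit outside [0, 1): a = %.4f, b = %.4f",
                 coeffs$a, coeffs$b))
  }
  coeffs
}

fit_origin_slope <- function(fields, role, floor_frac, min_px, what) {
  if (!is.list(fields) || length(fields) == 0L) {
    stop_myoquant(sprintf("no %s calibration fields supplied.", what),
                  "myoquant_insufficient_calibration")
  }
  x <- unlist(lapply(fields, function(f) as.numeric(field_channel(f, role))))
  y <- unlist(lapply(fields, function(f) as.numeric(field_channel(f, "FRET"))))
  keep <- x >= floor_frac * max(x)
  x <- x[keep]; y <- y[keep]
  if (length(x) < min_px || sum(x^2) == 0) {
    stop_myoquant(
      sprintf("%s calibration has %d pixel(s) above the floor; need >= %d.",
              what, length(x), min_px),
      "myoquant_insufficient_calibration")
  }
  slope <- sum(x * y) / sum(x^2)
  list(slope = slope, n = length(x), rss = sum((y - slope * x)^2))
}

#' @export
print.bleedthrough <- function(x, ...) {
  cat(sprintf("<bleedthrough> a = %.4f (donor, n = %d px), b = %.4f (acceptor, n = %d px)\n",
              x$a, x$n_px_donor, x$b, x$n_px_acceptor))
  invisible(x)
}

#' Write / read bleed-through coefficients as JSON
#' @param coeffs A `bleedthrough` object.
#' @param path JSON file path.
#' @return `path` invisibly; `read_bleedthrough()` returns the object.
#' @export
write_bleedthrough <- function(coeffs, path) {
  jsonlite::write_json(unclass(coeffs), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bleedthrough
#' @export
read_bleedthrough <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "bleedthrough")
}

#' Acceptor-normalized sensitized-emission FRET index of one field
#'
#' Per analyzed pixel the corrected FRET signal is
#' \deqn{nF = I_{FRET} - a I_{donor} - b I_{acceptor},}
#' clamped below at zero (negative sensitized emission is noise), then
#' divided by the acceptor intensity to normalize out acceptor-expression
#' variation. Analyzed pixels are those inside the cell mask whose acceptor
#' intensity reaches `acceptor_floor` (division stability).
#'
#' @param field Field with `DONOR`, `ACCEPTOR`, `FRET` channels.
#' @param coeffs A `bleedthrough` object (or list with `a`, `b`).
#' @param cell_mask Logical matrix delineating cells; `NULL` thresholds the
#'   donor channel (Otsu) and keeps components of at least `min_area` px.
#' @param acceptor_floor Minimum acceptor intensity; `NULL` uses the 95th
#'   percentile of the acceptor channel outside the cell mask (a cell-free
#'   estimate of background).
#' @param normalization `"pixelwise"` (mean of per-pixel `nF / I_acceptor`,
#'   the plugin-style index image) or `"ratio_of_means"`
#'   (`mean(nF) / mean(I_acceptor)`).
#' @param clamp_negative Clamp negative `nF` at 0 before normalizing.
#' @param min_area Minimum cell-component area for the default mask.
#' @param field_id Identifier carried into the result row.
#' @return One-row tibble: `field_id`, `mean_norm_index`, `n_px_analyzed`,
#'   `frac_clamped`.
#' @export
compute_fret_index <- function(field, coeffs, cell_mask = NULL,
                               acceptor_floor = NULL,
                               normalization = c("pixelwise", "ratio_of_means"),
                               clamp_negative = TRUE,
                               min_area = 50L,
                               field_id = NA_character_) {
  normalization <- match.arg(normalization)
  donor <- field_channel(field, "DONOR")
  acceptor <- field_channel(field, "ACCEPTOR")
  fret <- field_channel(field, "FRET")
  if (is.null(cell_mask)) {
    cell_mask <- clean_and_label(otsu_mask(donor), min_area_px = min_area) > 0L
  }
  stopifnot(is.logical(cell_mask), identical(dim(cell_mask), dim(donor)))
  if (!any(cell_mask)) {
    stop_myoquant("cell mask is empty; nothing to analyze.",
                  "myoquant_empty_analysis")
  }
  if (is.null(acceptor_floor)) {
    outside <- acceptor[!cell_mask]
    acceptor_floor <- if (length(outside)) {
      as.numeric(quantile(outside, 0.95))
    } else {
      0
    }
  }
  analyzed <- cell_mask & acceptor >= acceptor_floor
  n_px <- sum(analyzed)
  if (n_px == 0L) {
    stop_myoquant("no pixels pass the cell mask and acceptor floor.",
                  "myoquant_empty_analysis")
  }
  nf <- fret[analyzed] - coeffs$a * donor[analyzed] - coeffs$b * acceptor[analyzed]
  frac_clamped <- mean(nf < 0)
  if (clamp_negative) nf <- pmax(nf, 0)
  acc <- acceptor[analyzed]
  index <- switch(normalization,
                  pixelwise = mean(nf / acc),
                  ratio_of_means = mean(nf) / mean(acc))
  tibble(field_id = field_id,
         mean_norm_index = index,
         n_px_analyzed = n_px,
         frac_clamped = frac_clamped)
}

#' Paired pre/post-treatment change in the FRET index
#'
#' Pairs fields by id, reports the percent change of the mean normalized
#' index and a paired two-tailed t-test on the per-pair differences.
#'
#' @param pre,post Tibbles from [compute_fret_index()] (one row per field)
#'   with matching `field_id`s.
#' @return One-row tibble: `mean_pre`, `mean_post`, `pct_change`, `t`,
#'   `df`, `p_value`, `n_pairs`, `degenerate` (TRUE when the differences
#'   have zero variance; identical pre/post yields `pct_change = 0`,
#'   `p_value = 1`).
#' @export
fret_paired_change <- function(pre, post) {
  orphans <- c(setdiff(pre$field_id, post$field_id),
               setdiff(post$field_id, pre$field_id))
  if (length(orphans)) {
    stop_myoquant(sprintf("unpaired field id(s): %s",
                          paste(unique(orphans), collapse = ", ")),
                  "myoquant_pairing_error")
  }
  merged <- left_join(
    pre %>% select("field_id", pre_index = "mean_norm_index"),
    post %>% select("field_id", post_index = "mean_norm_index"),
    by = "field_id")
  d <- merged$post_index - merged$pre_index
  mean_pre <- mean(merged$pre_index)
  mean_post <- mean(merged$post_index)
  tt <- ttest_two_tailed(merged$post_index, merged$pre_index, paired = TRUE)
  degenerate <- tt$degenerate
  p <- tt$p
  if (degenerate && all(d == 0)) p <- 1
  tibble(mean_pre = mean_pre,
         mean_post = mean_post,
         pct_change = 100 * (mean_post - mean_pre) / mean_pre,
         t = tt$t, df = tt$df, p_value = p,
         n_pairs = nrow(merged),
         degenerate = degenerate)
}
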
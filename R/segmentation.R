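#' Otsu threshold of an intensity raster
#'
#' Picks the threshold that maximizes the between-class variance of the
#' intensity histogram, scanning every observed intensity level exhaustively
#' (exact on discrete data of any bit depth; on continuous data every
#' distinct value is a candidate). The mask is true strictly above the
#' threshold.
#'
#' @param raster 2D numeric matrix with at least two distinct values.
#' @return Logical matrix of the same shape with attribute `"threshold"`.
#' @examples
#' r <- matrix(c(rep(10, 90), rep(200, 10)), 10, 10)
#' m <- otsu_mask(r)
#' sum(m)  # the ten bright pixels
#' @export
otsu_mask <- function(raster) {
  stopifnot(is.matrix(raster), is.numeric(raster))
  th <- otsu_threshold_value(raster)
  mask <- raster > th
  attr(mask, "threshold") <- th
  mask
}

otsu_threshold_value <- function(raster) {
  vals <- sort(unique(as.numeric(raster)))
  if (length(vals) < 2L) {
    stop_myoquant("raster is constant; no threshold separates two classes.",
                  "myoquant_degenerate_input")
  }
  cnt <- as.numeric(table(factor(as.numeric(raster), levels = vals)))
  n <- sum(cnt)
  # candidate thresholds: all but the top level (mask must be non-trivial)
  w0 <- cumsum(cnt)[-length(cnt)]
  s0 <- cumsum(cnt * vals)[-length(cnt)]
  total <- sum(cnt * vals)
  w1 <- n - w0
  mu0 <- s0 / w0
  mu1 <- (total - s0) / w1
  bcv <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  k <- which.max(bcv)
  # midpoint between the maximizing level and the next observed level:
  # the same partition, but a threshold centered in any empty intensity gap
  (vals[k] + vals[k + 1L]) / 2
}

# connected-component labeling -------------------------------------------
# EBImage::bwlabel is 4-connected; 8-connectivity is obtained by merging
# labels that touch diagonally (union-find over label pairs).

label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask), is.matrix(mask), connectivity %in% c(4L, 8L))
  lab <- EBImage::bwlabel(mask * 1L)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (connectivity == 8L && max(lab) > 1L) {
    lab <- merge_diagonal_labels(lab)
  }
  relabel_contiguous(lab)
}

merge_diagonal_labels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1L, -1L])),  # down-right
    cbind(as.vector(lab[-1L, -nc]), as.vector(lab[-nr, -1L]))   # up-right
  )
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                   pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(max(lab))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1L]); b <- find(pairs[k, 2L])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_along(parent), find, integer(1L))
  lab[lab > 0L] <- root[lab[lab > 0L]]
  lab
}

relabel_contiguous <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L) {
    out <- lab
    attr(out, "n_labels") <- 0L
    return(out)
  }
  lut <- integer(max(ids))
  lut[ids] <- seq_along(ids)
  lab[lab > 0L] <- lut[lab[lab > 0L]]
  attr(lab, "n_labels") <- length(ids)
  lab
}

#' Clean a binary mask and label its connected components
#'
#' Optionally fills interior holes, removes components below a minimum
#' pixel area, and labels the survivors with contiguous positive integers
#' (0 = background).
#'
#' @param mask Logical matrix.
#' @param min_area_px Minimum component area in pixels (components strictly
#'   smaller are dropped).
#' @param fill_holes Fill interior holes before labeling.
#' @param connectivity 4 or 8 (default 8).
#' @return Integer label matrix with attribute `"n_labels"`.
#' @export
clean_and_label <- function(mask, min_area_px = 0L, fill_holes = FALSE,
                            connectivity = 8L) {
  stopifnot(is.logical(mask), is.matrix(mask), min_area_px >= 0)
  if (fill_holes && any(mask)) {
    mask <- matrix(as.integer(EBImage::fillHull(mask * 1L)) > 0L,
                   nrow(mask), ncol(mask))
  }
  lab <- label_components(mask, connectivity = connectivity)
  if (min_area_px > 0L && attr(lab, "n_labels") > 0L) {
    areas <- tabulate(lab[lab > 0L], nbins = attr(lab, "n_labels"))
    drop <- which(areas < min_area_px)
    if (length(drop)) {
      lab[lab %in% drop] <- 0L
      lab <- relabel_contiguous(lab)
    }
  }
  lab
}

#' Per-label areas and centroids
#'
#' @param labels Integer label matrix from [clean_and_label()].
#' @return Tibble with one row per label: `label`, `area_px`,
#'   `centroid_row`, `centroid_col` (1-based pixel coordinates, centroid =
#'   mean of member pixel indices).
#' @export
label_stats <- function(labels) {
  idx <- which(labels > 0L)
  if (length(idx) == 0L) {
    return(tibble(label = integer(), area_px = integer(),
                  centroid_row = double(), centroid_col = double()))
  }
  lab <- labels[idx]
  rows <- (idx - 1L) %% nrow(labels) + 1L
  cols <- (idx - 1L) %/% nrow(labels) + 1L
  area <- tabulate(lab)
  keep <- which(area > 0L)
  tibble(
    label = keep,
    area_px = area[keep],
    centroid_row = as.numeric(rowsum(rows, lab))[seq_along(keep)] / area[keep],
    centroid_col = as.numeric(rowsum(cols, lab))[seq_along(keep)] / area[keep]
  )
}

#' Subtract an acquisition background level from a raster
#'
#' Subtracts either a constant or a raster percentile, clamping at zero so
#' intensities stay nonnegative for downstream ratio and FRET math.
#'
#' @param raster Numeric matrix.
#' @param method `"constant"` or `"percentile"`.
#' @param param Background level (>= 0) for `"constant"`; percentile in
#'   (0, 100) for `"percentile"`.
#' @return Matrix `pmax(raster - b, 0)`.
#' @export
subtract_background <- function(raster, method = c("constant", "percentile"),
                                param) {
  method <- match.arg(method)
  stopifnot(is.matrix(raster), is.numeric(param), length(param) == 1L)
  if (method == "constant") {
    if (param < 0) {
      stop_myoquant("constant background must be >= 0.",
                    "myoquant_config_error")
    }
    b <- param
  } else {
    if (param <= 0 || param >= 100) {
      stop_myoquant("percentile must lie strictly between 0 and 100.",
                    "myoquant_config_error")
    }
    b <- as.numeric(quantile(raster, param / 100))
  }
  out <- pmax(raster - b, 0)
  attr(out, "background") <- b
  out
}
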
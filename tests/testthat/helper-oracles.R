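# Independent oracles, deliberately implemented differently from the
# package internals (queue flood fill vs union-find; explicit threshold
# scan vs vectorized cumsum; hand unit-conversion chains).

# flood-fill connected-component count/labels (BFS over an index queue)
oracle_label <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  offsets <- if (connectivity == 8L) {
    expand.grid(dr = -1:1, dc = -1:1)[-5, ]
  } else {
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      i <- queue[[1L]]; queue <- queue[-1L]
      r <- (i - 1L) %% nr + 1L
      c_ <- (i - 1L) %/% nr + 1L
      for (k in seq_len(nrow(offsets))) {
        rr <- r + offsets$dr[k]; cc <- c_ + offsets$dc[k]
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc) {
          j <- (cc - 1L) * nr + rr
          if (mask[j] && lab[j] == 0L) {
            lab[j] <- nxt
            queue <- c(queue, j)
          }
        }
      }
    }
  }
  attr(lab, "n_labels") <- nxt
  lab
}

# exhaustive between-class-variance scan over every observed level,
# reporting the midpoint between the maximizing level and the next one
oracle_otsu <- function(raster) {
  vals <- sort(unique(as.numeric(raster)))
  best <- -Inf; best_i <- 1L
  n <- length(raster)
  for (i in seq_len(length(vals) - 1L)) {
    lo <- raster <= vals[i]
    w0 <- sum(lo) / n; w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(raster[lo]) - mean(raster[!lo]))^2
    if (bcv > best) { best <- bcv; best_i <- i }
  }
  (vals[best_i] + vals[best_i + 1L]) / 2
}

# field with explicit constant compartments for R_mean arithmetic checks
make_compartment_field <- function(size = 32L, hras_golgi = 60,
                                   hras_membrane = 120, marker = 150,
                                   marker_bg = 5) {
  golgi <- membrane <- matrix(FALSE, size, size)
  golgi[5:9, 5:9] <- TRUE
  membrane[20:25, 4:28] <- TRUE
  hras <- matrix(10, size, size)
  hras[golgi] <- hras_golgi
  hras[membrane] <- hras_membrane
  rfp <- matrix(marker_bg, size, size); rfp[golgi] <- marker
  wga <- matrix(marker_bg, size, size); wga[membrane] <- marker
  list(field = new_field(list(HRAS_EGFP = hras, GOLGI_RFP = rfp,
                              PM_WGA = wga)),
       golgi = golgi, membrane = membrane)
}

# fields with an exact linear FRET relation for bleed-through checks
make_linear_fret_field <- function(a = 0.25, b = 0, size = 24L,
                                   donor = NULL, acceptor = NULL) {
  if (!is.null(donor)) size <- nrow(donor)
  if (!is.null(acceptor)) size <- nrow(acceptor)
  if (is.null(donor)) donor <- matrix(0, size, size)
  if (is.null(acceptor)) acceptor <- matrix(0, size, size)
  new_field(list(DONOR = donor, ACCEPTOR = acceptor,
                 FRET = a * donor + b * acceptor))
}
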
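make_disk_field <- function(centers, radii, size = 128L, level = 180,
                            bg = 5, mhc = NULL) {
  rows <- matrix(seq_len(size), size, size)
  cols <- t(rows)
  dapi <- matrix(bg, size, size)
  for (i in seq_len(nrow(centers))) {
    dapi[(rows - centers[i, 1])^2 + (cols - centers[i, 2])^2 <= radii[i]^2] <-
      level
  }
  if (is.null(mhc)) mhc <- matrix(bg, size, size)
  new_field(list(DAPI = dapi, MHC = mhc))
}

test_that("well-separated disks are counted with near-analytic areas", {
  withr::with_seed(14, {
    grid <- expand.grid(row = c(20, 50, 80, 110), col = c(20, 55, 90))
    centers <- as.matrix(grid)
    radii <- runif(12, 5, 8)
  })
  f <- make_disk_field(centers, radii)
  nuc <- segment_nuclei(f)
  expect_identical(nuc$n, 12L)
  # rasterized area within a one-pixel boundary ring of pi r^2
  ord <- order(nuc$nuclei$centroid_row, nuc$nuclei$centroid_col)
  ord_truth <- order(centers[, 1], centers[, 2])
  for (k in seq_len(12)) {
    r <- radii[ord_truth[k]]
    expect_lt(abs(nuc$nuclei$area_px[ord[k]] - pi * r^2), 2 * pi * r + 4)
  }
})

test_that("an empty DAPI channel yields an empty set with a warning", {
  f <- new_field(list(DAPI = matrix(5, 64, 64), MHC = matrix(5, 64, 64)))
  expect_warning(nuc <- segment_nuclei(f), "no nuclei")
  expect_identical(nuc$n, 0L)
  expect_identical(nrow(nuc$nuclei), 0L)
})

test_that("watershed splitting separates touching nuclei", {
  mt <- sim_myotube_field(n_nuclei = 40L, fused_fraction = 0.5,
                          n_touching_pairs = 8L, seed = 7)
  with_split <- segment_nuclei(mt$field, split_touching = TRUE)
  without <- segment_nuclei(mt$field, split_touching = FALSE)
  expect_identical(with_split$n, 40L)
  expect_lt(without$n, 40L)
})

test_that("disjoint bright stripes become distinct fibers", {
  mhc <- matrix(5, 128, 128)
  mhc[10:30, ] <- 150; mhc[60:80, ] <- 150; mhc[100:120, ] <- 150
  f <- new_field(list(DAPI = matrix(5, 128, 128), MHC = mhc))
  fib <- segment_fibers(f)
  expect_identical(attr(fib, "n_labels"), 3L)
  # a uniform channel reports zero fibers with a warning, not an error
  dim_f <- new_field(list(MHC = matrix(7, 64, 64)))
  expect_warning(fib0 <- segment_fibers(dim_f), "uniform")
  expect_identical(attr(fib0, "n_labels"), 0L)
})

test_that("fusion index is the percentage of centroids on fiber pixels", {
  centers <- cbind(row = seq(15, 105, by = 10), col = rep(c(30, 90), 5))
  radii <- rep(5, 10)
  mhc <- matrix(5, 128, 128)
  mhc[10:48, ] <- 150  # covers centroid rows 15, 25, 35, 45 -> 4 of 10 fused
  f <- make_disk_field(centers, radii, mhc = mhc)
  nuc <- segment_nuclei(f)
  fib <- segment_fibers(f)
  res <- fusion_index(nuc, fib)
  expect_equal(res$summary$fusion_index_pct, 40)
  expect_identical(res$summary$n_in_fiber,
                   sum(res$per_fiber$n_nuclei))
  # no fibers at all -> 0%
  res0 <- fusion_index(nuc, matrix(0L, 128, 128))
  expect_equal(res0$summary$fusion_index_pct, 0)
})

test_that("zero nuclei flag the index as undefined", {
  f <- new_field(list(DAPI = matrix(5, 64, 64), MHC = matrix(5, 64, 64)))
  suppressWarnings(nuc <- segment_nuclei(f))
  res <- fusion_index(nuc, matrix(0L, 64, 64))
  expect_true(res$summary$undefined)
  expect_true(is.na(res$summary$fusion_index_pct))
})

test_that("fusion index is invariant under fiber relabeling", {
  mt <- sim_myotube_field(seed = 23)
  nuc <- segment_nuclei(mt$field)
  fib <- segment_fibers(mt$field)
  base <- fusion_index(nuc, fib)
  # permute fiber labels
  n <- attr(fib, "n_labels")
  perm <- sample(seq_len(n))
  fib2 <- fib
  fib2[fib > 0L] <- perm[fib[fib > 0L]]
  again <- fusion_index(nuc, fib2)
  expect_equal(again$summary$fusion_index_pct, base$summary$fusion_index_pct)
  expect_equal(sort(again$per_fiber$n_nuclei), sort(base$per_fiber$n_nuclei))
})

test_that("adding a nucleus moves the index in the expected direction", {
  fibers <- matrix(0L, 64, 64); fibers[1:32, ] <- 1L
  base_centers <- cbind(c(10, 20, 50), c(20, 40, 20))
  mk_nuc <- function(centers) {
    f <- make_disk_field(centers, rep(4, nrow(centers)), size = 64L)
    segment_nuclei(f)
  }
  base <- fusion_index(mk_nuc(base_centers), fibers)$summary$fusion_index_pct
  plus_out <- fusion_index(mk_nuc(rbind(base_centers, c(55, 50))),
                           fibers)$summary$fusion_index_pct
  plus_in <- fusion_index(mk_nuc(rbind(base_centers, c(15, 55))),
                          fibers)$summary$fusion_index_pct
  expect_lt(plus_out, base)
  expect_gt(plus_in, base)
})

test_that("a nucleus touching a fiber only by its rim is not fused (centroid rule)", {
  fibers <- matrix(0L, 64, 64); fibers[1:20, ] <- 1L
  # center at row 24, radius 5: rim reaches row 19 (inside fiber), centroid out
  f <- make_disk_field(cbind(24, 32), 5, size = 64L)
  nuc <- segment_nuclei(f)
  cen <- fusion_index(nuc, fibers)
  expect_identical(cen$summary$n_in_fiber, 0L)
  # the area-overlap alternative also rejects it (< 50% overlap)
  ovl <- fusion_index(nuc, fibers, rule = "overlap50")
  expect_identical(ovl$summary$n_in_fiber, 0L)
  # but a nucleus mostly inside is accepted by both rules
  f2 <- make_disk_field(cbind(18, 32), 5, size = 64L)
  nuc2 <- segment_nuclei(f2)
  expect_identical(fusion_index(nuc2, fibers)$summary$n_in_fiber, 1L)
  expect_identical(fusion_index(nuc2, fibers,
                                rule = "overlap50")$summary$n_in_fiber, 1L)
})

test_that("nuclear areas convert to square micrometres", {
  f <- make_disk_field(cbind(32, 32), 5.6, size = 64L)
  f$pixel_size_um <- 0.5
  nuc <- segment_nuclei(f)
  stats <- nuclear_area_stats(nuc)
  expect_equal(stats$summary$unit, "um2")
  expect_equal(stats$summary$mean_area, nuc$nuclei$area_px * 0.25)
  # two synthetic nuclei of 80 and 120 px average to 100 px
  ns <- structure(list(labels = matrix(0L, 1, 1),
                       nuclei = tibble::tibble(label = 1:2,
                                               area_px = c(80, 120),
                                               centroid_row = c(1, 2),
                                               centroid_col = c(1, 2)),
                       n = 2L, pixel_size_um = NULL),
                  class = "nuclei_set")
  expect_equal(nuclear_area_stats(ns)$summary$mean_area, 100)
  expect_equal(nuclear_area_stats(ns)$summary$unit, "px")
})

test_that("mean recovered nuclear area approaches the analytic expectation", {
  areas <- numeric(0)
  for (seed in 1:5) {
    mt <- sim_myotube_field(n_nuclei = 40L, radius_range = c(5, 8),
                            seed = seed)
    nuc <- segment_nuclei(mt$field)
    areas <- c(areas, nuc$nuclei$area_px)
  }
  # E[pi r^2] for r ~ U(5, 8): pi * (25 + 40 + 64)/3
  expected <- pi * (8^3 - 5^3) / (3 * 3)
  expect_lt(abs(mean(areas) - expected) / expected, 0.05)
})
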
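test_that("bleed-through slopes are exact on noise-free linear controls", {
  withr::with_seed(1, donor <- matrix(runif(24 * 24, 50, 200), 24, 24))
  d_field <- make_linear_fret_field(a = 0.25, donor = donor)
  withr::with_seed(2, acceptor <- matrix(runif(24 * 24, 50, 200), 24, 24))
  a_field <- make_linear_fret_field(b = 0, acceptor = acceptor)  # FRET == 0
  co <- estimate_bleedthrough(list(d_field), list(a_field), floor_frac = 0,
                              min_px = 10L)
  expect_equal(co$a, 0.25)
  expect_equal(co$b, 0)
  expect_equal(co$rss_donor, 0)
})

test_that("bleed-through recovery is within 2% on noisy calibration sets", {
  fs <- sim_fret_set(a = 0.20, b = 0.10, seed = 31)
  co <- estimate_bleedthrough(fs$donor_only, fs$acceptor_only)
  expect_lt(abs(co$a - 0.20) / 0.20, 0.02)
  expect_lt(abs(co$b - 0.10) / 0.10, 0.02)
  # closed-form through-origin slope on one pooled set matches sum(xy)/sum(x2)
  x <- unlist(lapply(fs$donor_only, function(f) as.numeric(field_channel(f, "DONOR"))))
  y <- unlist(lapply(fs$donor_only, function(f) as.numeric(field_channel(f, "FRET"))))
  keep <- x >= 0.1 * max(x)
  expect_equal(co$a, sum(x[keep] * y[keep]) / sum(x[keep]^2))
})

test_that("too few calibration pixels raise an informative error", {
  tiny <- make_linear_fret_field(a = 0.2, donor = matrix(100, 3, 3))
  expect_error(estimate_bleedthrough(list(tiny), list(tiny), min_px = 100L),
               class = "myoquant_insufficient_calibration")
})

test_that("pure bleed-through yields a zero index; a known ratio is recovered", {
  withr::with_seed(7, {
    donor <- matrix(runif(30 * 30, 100, 200), 30, 30)
    acceptor <- matrix(runif(30 * 30, 100, 200), 30, 30)
  })
  co <- structure(list(a = 0.2, b = 0.1), class = "bleedthrough")
  pure <- new_field(list(DONOR = donor, ACCEPTOR = acceptor,
                         FRET = 0.2 * donor + 0.1 * acceptor))
  mask <- matrix(TRUE, 30, 30)
  res <- compute_fret_index(pure, co, cell_mask = mask, acceptor_floor = 0)
  expect_equal(res$mean_norm_index, 0)
  # every pixel sits at the clamp boundary
  expect_identical(res$n_px_analyzed, 900L)
  sens <- new_field(list(DONOR = donor, ACCEPTOR = acceptor,
                         FRET = 0.2 * donor + 0.1 * acceptor + 0.3 * acceptor))
  res2 <- compute_fret_index(sens, co, cell_mask = mask, acceptor_floor = 0)
  expect_equal(res2$mean_norm_index, 0.3)
  expect_equal(res2$frac_clamped, 0)
})

test_that("with a = b = 0 and no clamping the index is mean(FRET/acceptor)", {
  withr::with_seed(9, {
    acceptor <- matrix(runif(100, 100, 200), 10, 10)
    fret <- matrix(runif(100, 10, 50), 10, 10)
  })
  f <- new_field(list(DONOR = acceptor, ACCEPTOR = acceptor, FRET = fret))
  co <- structure(list(a = 0, b = 0), class = "bleedthrough")
  res <- compute_fret_index(f, co, cell_mask = matrix(TRUE, 10, 10),
                            acceptor_floor = 0)
  expect_equal(res$mean_norm_index, mean(fret / acceptor))
})

test_that("the index is gain-invariant", {
  fs <- sim_fret_set(s = 0.2, seed = 12)
  co <- estimate_bleedthrough(fs$donor_only, fs$acceptor_only)
  f <- fs$experimental[[1L]]
  mask <- fs$truth$cell_masks[[1L]]
  base <- compute_fret_index(f, co, cell_mask = mask, acceptor_floor = 100)
  scaled <- new_field(lapply(f$channels, `*`, 2.5))
  res <- compute_fret_index(scaled, co, cell_mask = mask,
                            acceptor_floor = 250)
  expect_equal(res$mean_norm_index, base$mean_norm_index)
  expect_equal(res$frac_clamped, base$frac_clamped)
})

test_that("the recovered index increases strictly with the true FRET fraction", {
  co <- NULL
  idx <- vapply(c(0, 0.1, 0.2, 0.4), function(s) {
    fs <- sim_fret_set(s = s, seed = 55)  # same seed: identical noise draw path
    if (is.null(co)) co <<- estimate_bleedthrough(fs$donor_only, fs$acceptor_only)
    mean(vapply(seq_along(fs$experimental), function(i) {
      compute_fret_index(fs$experimental[[i]], co,
                         cell_mask = fs$truth$cell_masks[[i]])$mean_norm_index
    }, double(1L)))
  }, double(1L))
  expect_true(all(diff(idx) > 0))
  # zero-FRET control is near zero, s = 0.2 recovered within 5%
  expect_lte(abs(idx[1L]), 0.01)
  expect_lt(abs(idx[3L] - 0.2) / 0.2, 0.05)
})

test_that("both normalization granularities are available and close on flat cells", {
  fs <- sim_fret_set(s = 0.2, seed = 18, n_experimental = 1L)
  co <- estimate_bleedthrough(fs$donor_only, fs$acceptor_only)
  f <- fs$experimental[[1L]]
  mask <- fs$truth$cell_masks[[1L]]
  px <- compute_fret_index(f, co, cell_mask = mask,
                           normalization = "pixelwise")$mean_norm_index
  rm_ <- compute_fret_index(f, co, cell_mask = mask,
                            normalization = "ratio_of_means")$mean_norm_index
  expect_lt(abs(px - rm_), 0.01)
})

test_that("paired change reports percent change, pairing errors and degeneracy", {
  pre <- tibble::tibble(field_id = c("f1", "f2"),
                        mean_norm_index = c(0.10, 0.10))
  post <- tibble::tibble(field_id = c("f1", "f2"),
                         mean_norm_index = c(0.13, 0.13))
  res <- fret_paired_change(pre, post)
  expect_equal(res$pct_change, 30)
  same <- fret_paired_change(pre, pre)
  expect_equal(same$pct_change, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)
  expect_error(fret_paired_change(pre, post[1L, ]), "f2",
               class = "myoquant_pairing_error")
})
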
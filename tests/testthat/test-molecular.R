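test_that("ddct folds follow the Livak arithmetic", {
  ct <- tibble::tibble(
    sample_id = rep(c("c1", "t1"), each = 2),
    condition = rep(c("ctrl", "trt"), each = 2),
    gene = rep(c("ref", "tgt"), 2),
    ct = c(10, 25, 10, 25))
  res <- relative_expression(ct, "ref", "ctrl")
  expect_equal(res$fold, c(1, 1))
  # one cycle lower at equal reference -> fold 2
  ct$ct[4] <- 24
  res2 <- relative_expression(ct, "ref", "ctrl")
  expect_equal(res2$ddct[res2$condition == "trt"], -1)
  expect_equal(res2$fold[res2$condition == "trt"], 2)
})

test_that("a random multi-condition table matches a hand-computed oracle", {
  sim <- sim_ct_table(
    folds = tidyr::expand_grid(condition = c("doxo", "pgj2", "at56"),
                               gene = c("Il6", "Tgfb1", "Myog")) |>
      dplyr::mutate(fold = c(4, 0.5, 1.7, 2.2, 0.9, 3.1, 1, 1.3, 0.4)),
    ct_noise_sd = 0.2, seed = 41)
  res <- relative_expression(sim$data, "Rn18s", "DMSO")
  # independent spreadsheet-style recomputation with base tools only
  tab <- as.data.frame(sim$data)
  ref <- tab[tab$gene == "Rn18s", c("sample_id", "ct")]
  oracle <- list()
  for (cond in unique(tab$condition)) for (gn in setdiff(unique(tab$gene), "Rn18s")) {
    rows <- tab[tab$condition == cond & tab$gene == gn, ]
    dcts <- rows$ct - ref$ct[match(rows$sample_id, ref$sample_id)]
    oracle[[paste(cond, gn)]] <- mean(dcts)
  }
  for (i in seq_len(nrow(res))) {
    key <- paste(res$condition[i], res$gene[i])
    ctrl_key <- paste("DMSO", res$gene[i])
    expect_equal(res$fold[i],
                 2^(-(oracle[[key]] - oracle[[ctrl_key]])),
                 tolerance = 1e-12)
  }
  expect_true(all(res$fold[res$condition == "DMSO"] == 1))
})

test_that("shifting one sample's Ct values uniformly leaves folds unchanged", {
  sim <- sim_ct_table(folds = tibble::tibble(condition = "doxo",
                                             gene = "Il6", fold = 3),
                      ct_noise_sd = 0.1, seed = 6)
  base <- relative_expression(sim$data, "Rn18s", "DMSO")
  shifted <- sim$data
  one <- shifted$sample_id == shifted$sample_id[1L]
  shifted$ct[one] <- shifted$ct[one] + 2.5
  expect_equal(relative_expression(shifted, "Rn18s", "DMSO")$fold, base$fold)
})

test_that("a sample missing the reference gene is named in the error", {
  ct <- tibble::tibble(sample_id = c("s1", "s1", "s2"),
                       condition = c("a", "a", "b"),
                       gene = c("ref", "tgt", "tgt"),
                       ct = c(10, 20, 21))
  expect_error(relative_expression(ct, "ref", "a"), "s2",
               class = "myoquant_validation_error")
})

test_that("doubling time is exact on ideal exponentials", {
  res <- doubling_time(tibble::tibble(time_hr = c(0, 24, 48, 72),
                                      count = c(1, 2, 4, 8) * 1e4))
  expect_equal(res$doubling_time_hr, 24)
  for (dt in c(3.7, 14, 57.24)) {
    sim <- sim_growth_curve(doubling_time_hr = dt, cv = 0)
    expect_equal(doubling_time(sim$data)$doubling_time_hr, dt)
  }
})

test_that("non-growing cultures are flagged rather than given a number", {
  res <- doubling_time(tibble::tibble(time_hr = c(0, 24, 48),
                                      count = c(1e4, 1e4, 1e4)))
  expect_true(res$non_growing)
  expect_true(is.na(res$doubling_time_hr))
  expect_error(doubling_time(tibble::tibble(time_hr = c(0, 24),
                                            count = c(1, 2))),
               class = "myoquant_validation_error")
})

test_that("standard curves reproduce exact lines and a least-squares oracle", {
  exact <- fit_standard_curve(tibble::tibble(conc_nM = c(100, 200, 300),
                                             area = c(1000, 2000, 3000)))
  expect_equal(exact$slope, 10)
  expect_equal(exact$intercept, 0)
  expect_equal(exact$r_squared, 1)
  two <- fit_standard_curve(tibble::tibble(conc_nM = c(100, 500),
                                           area = c(1000, 5000)))
  expect_equal(two$slope, 10)
  expect_equal(two$intercept, 0)
  # noisy standards: matches the closed-form least-squares solution
  sim <- sim_mrm_run(slope = 60, intercept = 500, area_cv = 0.03, seed = 3)
  curve <- fit_standard_curve(sim$standards)
  x <- sim$standards$conc_nM; y <- sim$standards$area
  slope_cf <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(curve$slope, slope_cf)
  expect_equal(curve$intercept, mean(y) - slope_cf * mean(x))
  expect_lt(abs(curve$slope - 60) / 60, 0.05)
  expect_error(fit_standard_curve(tibble::tibble(conc_nM = c(100, 100),
                                                 area = c(1, 2))),
               class = "myoquant_degenerate_fit")
})

test_that("lipid quantitation inverts the noise-free generator and converts units", {
  sim <- sim_mrm_run(sample_concs_nM = c(s1 = 250), area_cv = 0, n_cells = 1e6)
  curve <- fit_standard_curve(sim$standards)
  res <- quantify_lipid(sim$samples, curve, resuspension_volume_uL = 100)
  expect_equal(res$conc_nM, 250)
  # independent unit chain: 250e-9 mol/L * 100e-6 L * 316.43 g/mol -> fg/cell
  mass_fg <- 250e-9 * 100e-6 * 316.43 * 1e15
  expect_equal(res$mass_per_cell_fg, mass_fg / 1e6)
  expect_equal(res$total_mass_pg, mass_fg / 1e3)
  # back-calculation to the conditioned medium volume
  expect_equal(res$medium_conc_nM, 250 * 0.1 / 1.35)
  # area at the intercept -> concentration 0, not below the curve
  at0 <- quantify_lipid(tibble::tibble(sample_id = "z",
                                       area = curve$intercept),
                        curve, n_cells = 1e6)
  expect_equal(at0$conc_nM, 0)
  expect_false(at0$below_curve)
  below <- quantify_lipid(tibble::tibble(sample_id = "b",
                                         area = curve$intercept - 100),
                          curve, n_cells = 1e6)
  expect_true(below$below_curve)
  expect_equal(below$conc_nM, 0)
  expect_warning(quantify_lipid(tibble::tibble(sample_id = "hi", area = 1e9),
                                curve, n_cells = 1e6),
                 "extrapolat")
  expect_error(quantify_lipid(tibble::tibble(sample_id = "hi", area = 1e9),
                              curve, n_cells = 1e6, extrapolation = "error"),
               class = "myoquant_extrapolation_error")
})

test_that("MTT viability is the treated/control ratio of mean absorbances", {
  plate <- tibble::tibble(condition = rep(c("DMSO", "t1", "t2"), each = 3),
                          abs570 = c(1, 1, 1, 1, 1, 1, 0.5, 0.5, 0.5))
  res <- mtt_viability(plate, control = "DMSO")
  expect_equal(res$viability_pct[res$condition == "t1"], 100)
  expect_equal(res$viability_pct[res$condition == "t2"], 50)
  sim <- sim_mtt_plate(c(DMSO = 1.2, PGJ2 = 0.66), cv = 0.04, seed = 2)
  res2 <- mtt_viability(sim$data, control = "DMSO")
  hand <- 100 * mean(sim$data$abs570[sim$data$condition == "PGJ2"]) /
    mean(sim$data$abs570[sim$data$condition == "DMSO"])
  expect_equal(res2$viability_pct[res2$condition == "PGJ2"], hand)
  bad <- tibble::tibble(condition = c("DMSO", "DMSO"), abs570 = c(0, 0))
  expect_error(mtt_viability(bad, control = "DMSO"),
               class = "myoquant_validation_error")
})

test_that("the Student t-test matches the closed-form statistic and CDF", {
  expect_equal(ttest_two_tailed(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(ttest_two_tailed(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(ttest_two_tailed(c(1, 2, 3), c(1, 2, 3), paired = TRUE)$t, 0)
  withr::with_seed(10, { a <- rnorm(8); b <- rnorm(8, 0.8) })
  res <- ttest_two_tailed(a, b)
  sp2 <- ((7 * var(a)) + (7 * var(b))) / 14
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 8 + 1 / 8))
  expect_equal(res$t, t_hand)
  expect_equal(res$p, 2 * pt(abs(t_hand), 14, lower.tail = FALSE))
  degen <- ttest_two_tailed(c(2, 2, 2), c(5, 5, 5))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$p))
})

test_that("Dunnett with one comparison reduces to the t-test", {
  withr::with_seed(12, groups <- list(ctrl = rnorm(6), t1 = rnorm(6, 1)))
  dn <- dunnett_vs_control(groups, n_mc = 1e5, seed = 77)
  tt <- ttest_two_tailed(groups$t1, groups$ctrl)
  expect_equal(dn$t, tt$t)
  expect_lt(abs(dn$p_adjusted - tt$p), 0.005)
})

test_that("Dunnett adjusted p is never below unadjusted and grows with k", {
  withr::with_seed(30, groups <- list(ctrl = rnorm(5), t1 = rnorm(5, 0.8),
                                      t2 = rnorm(5, 0.2), t3 = rnorm(5, -0.5)))
  dn <- dunnett_vs_control(groups, n_mc = 1e5, seed = 5)
  expect_true(all(dn$p_adjusted >= dn$p_unadjusted))
  # same family, fewer comparisons: t1's adjusted p cannot exceed its value
  # in the larger family (Monte-Carlo slack allowed)
  dn1 <- dunnett_vs_control(groups[c("ctrl", "t1")], n_mc = 1e5, seed = 5)
  expect_lte(dn1$p_adjusted[dn1$group == "t1"],
             dn$p_adjusted[dn$group == "t1"] + 0.01)
  degen <- dunnett_vs_control(list(ctrl = c(1, 1), t1 = c(1, 1)),
                              n_mc = 100, seed = 1)
  expect_true(degen$degenerate)
  expect_error(dunnett_vs_control(list(ctrl = rnorm(4)), n_mc = 100, seed = 1),
               class = "myoquant_validation_error")
})

test_that("Dunnett adjusted p agrees with multcomp's integration", {
  skip_if_not_installed("multcomp")
  withr::with_seed(8, {
    df <- data.frame(
      value = c(rnorm(6), rnorm(6, 0.9), rnorm(6, 0.4), rnorm(6, 1.4)),
      group = factor(rep(c("ctrl", "t1", "t2", "t3"), each = 6),
                     levels = c("ctrl", "t1", "t2", "t3")))
  })
  dn <- dunnett_vs_control(df, control = "ctrl", n_mc = 2e5, seed = 3)
  fit <- stats::aov(value ~ group, data = df)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
  ref <- summary(gl, test = multcomp::adjusted("single-step"))
  expect_equal(dn$p_adjusted, as.numeric(ref$test$pvalues), tolerance = 0.01)
})

test_that("release fold change is the ratio of condition means", {
  d <- tibble::tibble(condition = rep(c("quiescent", "senescent"), each = 3),
                      value = c(1, 1.1, 0.9, 39, 41, 40))
  res <- release_fold_change(d, "quiescent", "senescent")
  expect_equal(res$fold, 40)
  expect_lt(res$p, 0.001)
})
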
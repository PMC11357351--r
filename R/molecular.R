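# r-squared without summary.lm (which warns on exact fits)
rsq <- function(fit, y) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(NA_real_)
  1 - sum(stats::residuals(fit)^2) / tss
}

#' Relative gene expression from Ct tables
#'
#' Livak-style quantification: per sample \eqn{\Delta C_T = C_T^{gene} -
#' C_T^{ref}}, averaged within each condition, then \eqn{\Delta\Delta C_T}
#' against the control condition and fold change \eqn{2^{-\Delta\Delta
#' C_T}}. `mode = "dct"` stops at per-sample \eqn{\Delta C_T} (the
#' presentation used for animal tissue, where no vehicle control exists).
#'
#' @param data Tibble with columns `sample_id`, `condition`, `gene`, `ct`.
#' @param reference_gene Internal loading control (e.g. 18s rRNA).
#' @param control_condition Experimental control (e.g. DMSO vehicle);
#'   required for `mode = "ddct"`.
#' @param mode `"ddct"` (condition-level folds) or `"dct"` (per-sample).
#' @return For `"ddct"`: tibble (`condition`, `gene`, `mean_dct`, `ddct`,
#'   `fold`), control rows having `fold = 1` by construction. For `"dct"`:
#'   tibble (`sample_id`, `condition`, `gene`, `dct`).
#' @examples
#' ct <- tibble::tibble(
#'   sample_id = rep(c("s1", "s2"), each = 2),
#'   condition = rep(c("DMSO", "Doxo"), each = 2),
#'   gene = rep(c("Rn18s", "Il6"), 2),
#'   ct = c(10, 25, 10, 24))
#' relative_expression(ct, "Rn18s", "DMSO")  # Il6 fold = 2 in Doxo
#' @export
relative_expression <- function(data, reference_gene, control_condition = NULL,
                                mode = c("ddct", "dct")) {
  mode <- match.arg(mode)
  data <- as_tibble(data)
  req <- c("sample_id", "condition", "gene", "ct")
  if (!all(req %in% names(data))) {
    stop_myoquant(sprintf("Ct table must have columns: %s.",
                          paste(req, collapse = ", ")),
                  "myoquant_validation_error")
  }
  if (!all(is.finite(data$ct)) || any(data$ct <= 0)) {
    stop_myoquant("Ct values must be finite and > 0.",
                  "myoquant_validation_error")
  }
  ref <- data %>% filter(.data$gene == reference_gene) %>%
    select("sample_id", ref_ct = "ct")
  missing_ref <- setdiff(unique(data$sample_id), ref$sample_id)
  if (length(missing_ref)) {
    stop_myoquant(sprintf("sample(s) missing the reference gene '%s': %s",
                          reference_gene, paste(missing_ref, collapse = ", ")),
                  "myoquant_validation_error")
  }
  dct <- data %>% filter(.data$gene != reference_gene) %>%
    left_join(ref, by = "sample_id") %>%
    mutate(dct = .data$ct - .data$ref_ct)
  if (mode == "dct") {
    return(dct %>% select("sample_id", "condition", "gene", "dct"))
  }
  if (is.null(control_condition) || !control_condition %in% data$condition) {
    stop_myoquant("a control condition present in the table is required for ddct.",
                  "myoquant_validation_error")
  }
  cond_means <- dct %>% group_by(.data$condition, .data$gene) %>%
    summarise(mean_dct = mean(.data$dct), .groups = "drop")
  ctrl <- cond_means %>% filter(.data$condition == control_condition) %>%
    select("gene", ctrl_dct = "mean_dct")
  cond_means %>% left_join(ctrl, by = "gene") %>%
    mutate(ddct = .data$mean_dct - .data$ctrl_dct,
           fold = 2^(-.data$ddct)) %>%
    select("condition", "gene", "mean_dct", "ddct", "fold")
}

#' Cell doubling time from a growth curve
#'
#' Counts are normalized to the count at time zero (absorbing plating
#' efficiency); the doubling time is the reciprocal of the ordinary
#' least-squares slope of log2(normalized count) against time.
#'
#' @param data Tibble with columns `time_hr` (strictly increasing, starting
#'   at 0) and `count` (> 0); at least 3 points.
#' @return One-row tibble: `slope` (doublings/hr), `doubling_time_hr`,
#'   `r_squared`, `non_growing` (TRUE with `doubling_time_hr = NA` when the
#'   slope is not positive).
#' @examples
#' doubling_time(tibble::tibble(time_hr = c(0, 24, 48, 72),
#'                              count = c(1, 2, 4, 8) * 1e4))
#' @export
doubling_time <- function(data) {
  data <- as_tibble(data)
  stopifnot(all(c("time_hr", "count") %in% names(data)))
  t <- data$time_hr; n <- data$count
  if (length(t) < 3L) {
    stop_myoquant("at least 3 time points are required.",
                  "myoquant_validation_error")
  }
  if (any(diff(t) <= 0) || t[1L] != 0) {
    stop_myoquant("time must start at 0 and increase strictly.",
                  "myoquant_validation_error")
  }
  if (any(n <= 0)) {
    stop_myoquant("counts must be positive.", "myoquant_validation_error")
  }
  y <- log2(n / n[1L])
  fit <- lm(y ~ t)
  m <- unname(coef(fit)[2L])
  r2 <- rsq(fit, y)
  non_growing <- m <= 0
  tibble(slope = m,
         doubling_time_hr = if (non_growing) NA_real_ else 1 / m,
         r_squared = r2,
         non_growing = non_growing)
}

#' Fit an MRM standard curve
#'
#' Ordinary least-squares line of mass-spectrometry peak area on nominal
#' standard concentration.
#'
#' @param data Tibble with columns `conc_nM` (>= 2 distinct values) and
#'   `area`.
#' @return Object of class `standard_curve`: the `lm` fit, the points,
#'   `slope`, `intercept`, `r_squared`.
#' @export
fit_standard_curve <- function(data) {
  data <- as_tibble(data)
  stopifnot(all(c("conc_nM", "area") %in% names(data)))
  if (length(unique(data$conc_nM)) < 2L) {
    stop_myoquant("at least 2 distinct standard concentrations are required.",
                  "myoquant_degenerate_fit")
  }
  fit <- lm(area ~ conc_nM, data = data)
  structure(list(fit = fit,
                 points = data,
                 slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r_squared = rsq(fit, data$area)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> area = %.4g * conc + %.4g (r^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' @export
tidy.standard_curve <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = c("intercept", "slope"),
         estimate = s[, 1L], std_error = s[, 2L],
         statistic = s[, 3L], p_value = s[, 4L])
}

#' @export
glance.standard_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared, n = nrow(x$points))
}

#' Plot a standard curve with its fitted line
#' @param object A `standard_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$conc_nM, y = .data$area)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "15d-PGJ2 standard (nM)", y = "MRM peak area") +
    ggplot2::theme_minimal()
}

#' Quantify 15d-PGJ2 from sample peak areas
#'
#' Back-calculates each sample's concentration from the standard curve,
#' converts to total mass via the molecular weight, and normalizes per
#' cell. Concentrations are reported both at the resuspension volume (what
#' the instrument saw) and back-calculated to the original conditioned
#' medium volume; negative back-calculated concentrations are clamped to 0
#' and flagged `below_curve`.
#'
#' @param samples Tibble with columns `sample_id`, `area`, and `n_cells`
#'   (or pass a scalar `n_cells`).
#' @param curve A [fit_standard_curve()] result.
#' @param n_cells Scalar cell count used when `samples` lacks an `n_cells`
#'   column.
#' @param resuspension_volume_uL Extract resuspension volume (default 100).
#' @param medium_volume_mL Conditioned-medium volume the lipid came from
#'   (default 1.35).
#' @param mw Analyte molecular weight in g/mol (default [MW_15D_PGJ2]).
#' @param extrapolation `"warn"` (default) or `"error"` when an area
#'   exceeds the top standard's fitted area.
#' @return Tibble per sample: `conc_nM` (resuspension), `medium_conc_nM`,
#'   `total_mass_pg`, `mass_per_cell_fg`, `below_curve`, `above_curve`.
#' @export
quantify_lipid <- function(samples, curve, n_cells = NULL,
                           resuspension_volume_uL = 100,
                           medium_volume_mL = 1.35,
                           mw = MW_15D_PGJ2,
                           extrapolation = c("warn", "error")) {
  extrapolation <- match.arg(extrapolation)
  stopifnot(inherits(curve, "standard_curve"),
            resuspension_volume_uL > 0, medium_volume_mL > 0, mw > 0)
  if (curve$slope == 0) {
    stop_myoquant("standard curve slope is zero; unusable.",
                  "myoquant_degenerate_fit")
  }
  samples <- as_tibble(samples)
  stopifnot(all(c("sample_id", "area") %in% names(samples)))
  if (!"n_cells" %in% names(samples)) {
    if (is.null(n_cells)) {
      stop_myoquant("supply `n_cells` as a column or scalar.",
                    "myoquant_validation_error")
    }
    samples$n_cells <- n_cells
  }
  if (any(samples$n_cells <= 0)) {
    stop_myoquant("n_cells must be positive.", "myoquant_validation_error")
  }
  top_area <- curve$intercept + curve$slope * max(curve$points$conc_nM)
  above <- samples$area > top_area
  if (any(above)) {
    msg <- sprintf("%d sample area(s) above the top standard; extrapolating.",
                   sum(above))
    if (extrapolation == "error") {
      stop_myoquant(msg, "myoquant_extrapolation_error")
    }
    warn(msg)
  }
  conc_raw <- (samples$area - curve$intercept) / curve$slope
  below <- conc_raw < 0
  conc <- pmax(conc_raw, 0)
  vol_L <- resuspension_volume_uL * 1e-6
  moles <- conc * 1e-9 * vol_L                 # nM * L -> mol
  total_mass_pg <- moles * mw * 1e12           # g -> pg
  samples %>%
    mutate(conc_nM = conc,
           medium_conc_nM = conc * (resuspension_volume_uL / 1000) /
             medium_volume_mL,
           total_mass_pg = total_mass_pg,
           mass_per_cell_fg = total_mass_pg * 1e3 / .data$n_cells,
           below_curve = below,
           above_curve = above)
}

#' MTT viability relative to control
#'
#' Mean 570 nm absorbance of each treated condition as a percentage of the
#' control mean.
#'
#' @param data Tibble with columns `condition` and `abs570`.
#' @param control Control condition name.
#' @return Tibble (`condition`, `n`, `mean_abs570`, `viability_pct`), the
#'   control row at 100.
#' @export
mtt_viability <- function(data, control) {
  data <- as_tibble(data)
  stopifnot(all(c("condition", "abs570") %in% names(data)))
  if (!control %in% data$condition) {
    stop_myoquant(sprintf("control condition '%s' not present.", control),
                  "myoquant_validation_error")
  }
  ctrl_mean <- mean(data$abs570[data$condition == control])
  if (!is.finite(ctrl_mean) || ctrl_mean <= 0) {
    stop_myoquant("control mean absorbance must be positive.",
                  "myoquant_validation_error")
  }
  data %>% group_by(.data$condition) %>%
    summarise(n = dplyr::n(), mean_abs570 = mean(.data$abs570),
              .groups = "drop") %>%
    mutate(viability_pct = 100 * .data$mean_abs570 / ctrl_mean)
}

#' Two-tailed Student t-test
#'
#' Classical Student statistic: pooled-variance unpaired test, or the
#' paired test on difference scores. Groups whose pooled variance is zero
#' are flagged degenerate (p undefined, except identical paired groups
#' where t = 0).
#'
#' @param group_a,group_b Numeric vectors (each n >= 2; equal n if paired).
#' @param paired Paired test flag.
#' @return One-row tibble: `t`, `df`, `p`, `degenerate`.
#' @export
ttest_two_tailed <- function(group_a, group_b, paired = FALSE) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  if (paired && length(group_a) != length(group_b)) {
    stop_myoquant("paired test requires equal group sizes.",
                  "myoquant_validation_error")
  }
  degenerate <- if (paired) {
    sd(group_a - group_b) == 0
  } else {
    sd(group_a) == 0 && sd(group_b) == 0
  }
  if (degenerate) {
    same <- if (paired) all(group_a == group_b) else
      mean(group_a) == mean(group_b)
    return(tibble(t = if (same) 0 else NA_real_,
                  df = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  tt <- t.test(group_a, group_b, paired = paired, var.equal = TRUE,
               alternative = "two.sided")
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, degenerate = FALSE)
}

#' Dunnett's many-to-one comparisons versus a control
#'
#' Computes the Dunnett statistics \eqn{t_i = (\bar y_i - \bar y_0) /
#' (s\sqrt{1/n_i + 1/n_0})} with the variance pooled across all groups, and
#' estimates two-sided family-wise adjusted p-values by Monte-Carlo
#' sampling of the null distribution of \eqn{\max_i |T_i|} (shared control
#' variate, pooled chi-square scale), which captures the comparisons'
#' correlation exactly. Adjusted p-values are never below the unadjusted
#' two-sided t-test p.
#'
#' @param data Tibble with columns `value` and `group`, or a named list of
#'   numeric vectors.
#' @param control Control group name (default: first group).
#' @param n_mc Monte-Carlo draws (default 1e5).
#' @param seed RNG seed for the draws.
#' @return Tibble per treatment group: `group`, `n`, `estimate`
#'   (mean difference vs control), `t`, `df`, `p_unadjusted`, `p_adjusted`,
#'   `degenerate`.
#' @export
dunnett_vs_control <- function(data, control = NULL, n_mc = 1e5, seed = 1L) {
  if (is.list(data) && !is.data.frame(data)) {
    data <- tibble(group = rep(names(data), lengths(data)),
                   value = unlist(data, use.names = FALSE))
  }
  data <- as_tibble(data)
  stopifnot(all(c("value", "group") %in% names(data)))
  groups <- unique(data$group)
  if (is.null(control)) control <- groups[[1L]]
  if (!control %in% groups) {
    stop_myoquant(sprintf("control group '%s' not present.", control),
                  "myoquant_validation_error")
  }
  trt <- setdiff(groups, control)
  if (length(trt) == 0L) {
    stop_myoquant("at least one treatment group is required.",
                  "myoquant_validation_error")
  }
  split_vals <- split(data$value, data$group)
  ns <- vapply(split_vals, length, integer(1L))
  if (any(ns < 2L)) {
    stop_myoquant("every group needs n >= 2.", "myoquant_validation_error")
  }
  means <- vapply(split_vals, mean, double(1L))
  k <- length(trt)
  N <- sum(ns)
  df <- N - (k + 1L)
  ss <- sum(vapply(split_vals, function(v) sum((v - mean(v))^2), double(1L)))
  s2 <- ss / df
  if (s2 == 0) {
    return(tibble(group = trt, n = unname(ns[trt]),
                  estimate = unname(means[trt] - means[control]),
                  t = NA_real_, df = df, p_unadjusted = NA_real_,
                  p_adjusted = NA_real_, degenerate = TRUE))
  }
  se <- sqrt(s2 * (1 / ns[trt] + 1 / ns[control]))
  tstat <- (means[trt] - means[control]) / se
  p_unadj <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  # Monte-Carlo null of max_i |T_i|: control variate drawn first so that
  # results for the first k' comparisons are reproducible across k >= k'
  maxT <- withr::with_seed(as.integer(seed), {
    s_draw <- sqrt(rchisq(n_mc, df) / df)
    z0 <- rnorm(n_mc) / sqrt(ns[control])
    m <- matrix(0, n_mc, k)
    for (j in seq_len(k)) {
      zj <- rnorm(n_mc) / sqrt(ns[trt[j]])
      m[, j] <- abs(zj - z0) / (s_draw * sqrt(1 / ns[trt[j]] + 1 / ns[control]))
    }
    do.call(pmax, as.data.frame(m))
  })
  p_adj <- vapply(unname(abs(tstat)), function(ti) mean(maxT >= ti),
                  double(1L))
  tibble(group = trt, n = unname(ns[trt]),
         estimate = unname(means[trt] - means[control]),
         t = unname(tstat), df = df,
         p_unadjusted = unname(p_unadj),
         p_adjusted = pmax(p_adj, unname(p_unadj)),
         degenerate = FALSE)
}

#' Fold change in released 15d-PGJ2 between two conditions
#'
#' Ratio of mean per-cell (or per-sample) 15d-PGJ2 amounts between a
#' treated (senescent) and a reference (quiescent) condition, with a
#' two-tailed Student t-test.
#'
#' @param data Tibble with columns `condition` and `value` (e.g.
#'   `mass_per_cell_fg` from [quantify_lipid()]).
#' @param reference,treated Condition names.
#' @return One-row tibble: `mean_reference`, `mean_treated`, `fold`, `p`.
#' @export
release_fold_change <- function(data, reference, treated) {
  data <- as_tibble(data)
  stopifnot(all(c("condition", "value") %in% names(data)))
  ref <- data$value[data$condition == reference]
  trt <- data$value[data$condition == treated]
  if (length(ref) == 0L || length(trt) == 0L) {
    stop_myoquant("both conditions must be present.",
                  "myoquant_validation_error")
  }
  if (mean(ref) <= 0) {
    stop_myoquant("reference mean must be positive to form a fold change.",
                  "myoquant_validation_error")
  }
  p <- if (length(ref) >= 2L && length(trt) >= 2L) {
    ttest_two_tailed(trt, ref)$p
  } else NA_real_
  tibble(mean_reference = mean(ref), mean_treated = mean(trt),
         fold = mean(trt) / mean(ref), p = p)
}
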
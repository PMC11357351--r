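# Synthetic-data generators. Every generator takes one explicit seed, uses
# no global RNG state (withr::with_seed), and returns its ground truth so
# downstream recovery can be scored. The shared imaging noise model is
# Poisson shot noise on the expected photon count plus additive Gaussian
# read noise, clamped at zero. SNR is defined as
# (signal mean - background mean) / background sd and recorded in the truth.

add_imaging_noise <- function(expectation, read_sd, shot_noise = TRUE) {
  x <- if (shot_noise) {
    matrix(rpois(length(expectation), lambda = expectation),
           nrow(expectation), ncol(expectation))
  } else {
    expectation
  }
  if (read_sd > 0) {
    x <- x + matrix(rnorm(length(x), sd = read_sd), nrow(x), ncol(x))
  }
  pmax(x, 0)
}

read_sd_for_snr <- function(signal, background, snr) {
  # solve (signal-bg)/sqrt(bg + sd^2) = snr for the Gaussian read sd,
  # Poisson variance of the background included
  sqrt(max(((signal - background) / snr)^2 - background, 0))
}

new_ground_truth <- function(generator, seed, params, ...) {
  structure(c(list(generator = generator, seed = seed, params = params),
              list(...)),
            class = "ground_truth")
}

#' Write a ground-truth sidecar as JSON
#'
#' Scalar parameters and checksums go into the JSON; pixel masks, when
#' present, are written as 8-bit TIFFs next to it.
#'
#' @param truth A `ground_truth` object.
#' @param path JSON path; mask TIFFs are derived from it.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- unclass(truth)
  # named atomic vectors must serialize as JSON objects, not bare arrays
  out <- lapply(out, function(x) {
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
  })
  mask_names <- names(out)[vapply(out, function(x)
    is.matrix(x) && is.logical(x), logical(1L))]
  for (nm in mask_names) {
    mask_path <- sub("\\.json$", paste0("_", nm, ".tif"), path)
    write_mask(out[[nm]], mask_path)
    out[[nm]] <- basename(mask_path)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# cell placement: rejection-sample centers on a field so that bounding
# circles (radius + margin) do not overlap; bounded retries
place_centers <- function(size, n, radius, margin = 2, max_tries = 2000L) {
  centers <- matrix(NA_real_, 0L, 2L)
  tries <- 0L
  lo <- radius + margin + 1
  hi <- size - radius - margin
  if (hi <= lo) {
    stop_myoquant("objects do not fit in the field.", "myoquant_placement_error")
  }
  while (nrow(centers) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop_myoquant(
        sprintf("could not place %d objects of radius %.0f in a %dx%d field.",
                n, radius, size, size),
        "myoquant_placement_error")
    }
    cand <- runif(2L, lo, hi)
    if (nrow(centers) == 0L ||
        all(sqrt(rowSums(t(t(centers) - cand)^2)) > 2 * (radius + margin))) {
      centers <- rbind(centers, cand)
    }
  }
  centers
}

#' Generate a synthetic HRas localization field
#'
#' Each cell is an axis-aligned elliptical annulus of plasma membrane
#' (bright in `PM_WGA`) around a cytosolic interior with one compact Golgi
#' blob (bright in `GOLGI_RFP`). The HRas channel's expectation is
#' `base_intensity` on membrane pixels, `g * base_intensity` on Golgi
#' pixels, and 10% of base in the cytosol, so the true Golgi-to-membrane
#' mean ratio is exactly `g`.
#'
#' @param size Field edge length (px).
#' @param n_cells Cells per field.
#' @param g True Golgi-to-membrane intensity ratio (> 0).
#' @param base_intensity HRas expectation at the membrane (counts).
#' @param snr Signal-to-noise ratio (signal minus background over
#'   background sd); sets the Gaussian read noise. `Inf` disables all noise.
#' @param marker_intensity Marker channels' bright level.
#' @param seed RNG seed.
#' @return List: `field` and `truth` (`ground_truth` with `golgi_mask`,
#'   `membrane_mask`, `g`, `read_sd`, per-channel sums).
#' @export
sim_localization_field <- function(size = 192L, n_cells = 6L, g = 1,
                                   base_intensity = 200, snr = 10,
                                   marker_intensity = 150, seed = 1L) {
  stopifnot(g > 0, snr > 0)
  withr::with_seed(as.integer(seed), {
    bg <- 0.05 * base_intensity
    noise_on <- is.finite(snr)
    read_sd <- if (noise_on) read_sd_for_snr(base_intensity, bg, snr) else 0
    golgi <- membrane <- interior <- matrix(FALSE, size, size)
    rows <- matrix(seq_len(size), size, size)
    cols <- t(rows)
    if (n_cells > 0L) {
      a_max <- 20
      centers <- place_centers(size, n_cells, radius = a_max, margin = 2)
      for (i in seq_len(n_cells)) {
        a <- runif(1, 16, 20); b <- runif(1, 12, 16)
        cy <- centers[i, 1L]; cx <- centers[i, 2L]
        d <- ((cols - cx) / a)^2 + ((rows - cy) / b)^2
        membrane <- membrane | (d >= 0.78 & d <= 1)
        inside <- d < 0.78
        interior <- interior | inside
        # compact Golgi blob offset from the cell center, inside the cytosol
        ang <- runif(1, 0, 2 * pi)
        gx <- cx + 0.3 * a * cos(ang); gy <- cy + 0.3 * b * sin(ang)
        rg <- runif(1, 6, 8)
        blob <- ((cols - gx)^2 + (rows - gy)^2 <= rg^2) & inside
        golgi <- golgi | blob
      }
    }
    cytosol <- interior & !golgi
    hras <- matrix(bg, size, size)
    hras[cytosol] <- 0.1 * base_intensity
    hras[membrane] <- base_intensity
    hras[golgi] <- g * base_intensity
    marker_bg <- 5
    wga <- matrix(marker_bg, size, size); wga[membrane] <- marker_intensity
    rfp <- matrix(marker_bg, size, size); rfp[golgi] <- marker_intensity
    channels <- list(HRAS_EGFP = hras, GOLGI_RFP = rfp, PM_WGA = wga)
    if (noise_on) {
      channels <- lapply(channels, add_imaging_noise, read_sd = read_sd)
    }
    field <- new_field(channels, meta = list(generator = "sim_localization_field",
                                             seed = seed))
    truth <- new_ground_truth(
      "sim_localization_field", seed,
      params = list(size = size, n_cells = n_cells, g = g,
                    base_intensity = base_intensity, snr = snr,
                    marker_intensity = marker_intensity),
      g = g, read_sd = read_sd,
      golgi_mask = golgi, membrane_mask = membrane,
      channel_sums = vapply(field$channels, sum, double(1L)))
    list(field = field, truth = truth)
  })
}

#' Generate a sensitized-emission FRET acquisition set
#'
#' Produces donor-only and acceptor-only calibration fields plus
#' experimental fields. On cell pixels the transfer-channel expectation is
#' `a * donor + b * acceptor` for calibration fields and additionally
#' `s * acceptor` of true sensitized emission for experimental fields. The
#' default intensity regime is shot-noise-limited confocal detection
#' (photon counts in the thousands, small read noise).
#'
#' @param a,b True donor and acceptor bleed-through fractions in `[0, 1)`.
#' @param s True sensitized-emission fraction (>= 0).
#' @param donor_level,acceptor_level Expected counts on cell pixels.
#' @param background Expected counts outside cells.
#' @param read_sd Gaussian read-noise sd; 0 with `shot_noise = FALSE` gives
#'   noise-free fields.
#' @param shot_noise Apply Poisson shot noise.
#' @param size Field edge length (px).
#' @param n_calibration Fields per single-label calibration set.
#' @param n_experimental Experimental (double-label) fields.
#' @param seed RNG seed.
#' @return List: `donor_only`, `acceptor_only`, `experimental` (lists of
#'   fields; experimental fields are named), and `truth` (includes the
#'   per-field cell masks as `cell_masks`, the SNR reached, and parameters).
#' @export
sim_fret_set <- function(a = 0.2, b = 0.1, s = 0.2,
                         donor_level = 1500, acceptor_level = 2000,
                         background = 20, read_sd = 10, shot_noise = TRUE,
                         size = 96L, n_calibration = 10L,
                         n_experimental = 5L, seed = 1L) {
  stopifnot(a >= 0, a < 1, b >= 0, b < 1, s >= 0)
  withr::with_seed(as.integer(seed), {
    rows <- matrix(seq_len(size), size, size)
    cols <- t(rows)
    make_cell_mask <- function() {
      cy <- runif(1, size * 0.4, size * 0.6)
      cx <- runif(1, size * 0.4, size * 0.6)
      a_ax <- runif(1, size * 0.25, size * 0.33)
      b_ax <- runif(1, size * 0.2, size * 0.28)
      ((cols - cx) / a_ax)^2 + ((rows - cy) / b_ax)^2 <= 1
    }
    noisy <- function(m) add_imaging_noise(m, read_sd, shot_noise)
    flat <- function(level, mask) {
      m <- matrix(background, size, size); m[mask] <- level; m
    }
    make_field <- function(kind) {
      cell <- make_cell_mask()
      donor_e <- acceptor_e <- matrix(0, size, size)
      if (kind != "acceptor_only") donor_e <- flat(donor_level, cell)
      if (kind != "donor_only") acceptor_e <- flat(acceptor_level, cell)
      s_here <- if (kind == "experimental") s else 0
      fret_e <- a * donor_e + b * acceptor_e
      fret_e[cell] <- fret_e[cell] + s_here * acceptor_e[cell]
      f <- new_field(list(DONOR = noisy(donor_e), ACCEPTOR = noisy(acceptor_e),
                          FRET = noisy(fret_e)),
                     meta = list(generator = "sim_fret_set", kind = kind,
                                 seed = seed))
      list(field = f, cell = cell)
    }
    donor_only <- lapply(seq_len(n_calibration), function(i) make_field("donor_only"))
    acceptor_only <- lapply(seq_len(n_calibration), function(i) make_field("acceptor_only"))
    experimental <- lapply(seq_len(n_experimental), function(i) make_field("experimental"))
    names(experimental) <- sprintf("exp_%03d", seq_len(n_experimental))
    bg_sd <- sqrt(background + read_sd^2)
    truth <- new_ground_truth(
      "sim_fret_set", seed,
      params = list(a = a, b = b, s = s, donor_level = donor_level,
                    acceptor_level = acceptor_level, background = background,
                    read_sd = read_sd, shot_noise = shot_noise, size = size,
                    n_calibration = n_calibration,
                    n_experimental = n_experimental),
      a = a, b = b, s = s,
      snr = (acceptor_level - background) / max(bg_sd, .Machine$double.eps),
      cell_masks = lapply(experimental, `[[`, "cell"))
    list(donor_only = lapply(donor_only, `[[`, "field"),
         acceptor_only = lapply(acceptor_only, `[[`, "field"),
         experimental = lapply(experimental, `[[`, "field"),
         truth = truth)
  })
}

#' Generate a synthetic myotube field
#'
#' MHC channel: `n_fibers` bright horizontal stripes (fibers). DAPI
#' channel: `n_nuclei` disks whose centers are placed so that exactly
#' `round(fused_fraction * n_nuclei)` lie inside stripes (with margin) and
#' the rest in the gaps; nuclei never touch unless `n_touching_pairs`
#' requests overlapping pairs for watershed testing.
#'
#' @param size Field edge length (px).
#' @param n_fibers Number of stripes.
#' @param n_nuclei Total nuclei.
#' @param fused_fraction Fraction of nuclei placed inside fibers.
#' @param radius_range Nucleus radius range (px), sampled uniformly.
#' @param n_touching_pairs Of the placed nuclei, this many extra pairs are
#'   placed touching (for split testing); all counted in `n_nuclei`.
#' @param nucleus_intensity,fiber_intensity,background Expected levels.
#' @param noise_sd Additive Gaussian noise sd (0 = noise-free).
#' @param pixel_size_um Optional physical pixel size carried on the field.
#' @param seed RNG seed.
#' @return List: `field` (DAPI + MHC) and `truth` with `centers` tibble
#'   (`row`, `col`, `radius`, `fused`), `fiber_mask`, `n_fibers`,
#'   `fused_fraction`.
#' @export
sim_myotube_field <- function(size = 256L, n_fibers = 4L, n_nuclei = 50L,
                              fused_fraction = 0.6, radius_range = c(5, 8),
                              n_touching_pairs = 0L,
                              nucleus_intensity = 180, fiber_intensity = 150,
                              background = 5, noise_sd = 0,
                              pixel_size_um = NULL, seed = 1L) {
  stopifnot(fused_fraction >= 0, fused_fraction <= 1,
            2L * n_touching_pairs <= n_nuclei)
  withr::with_seed(as.integer(seed), {
    # horizontal stripes: fiber i occupies rows [top, top + h)
    h <- max(4L, floor(size / (2L * max(n_fibers, 1L))))
    gap <- if (n_fibers > 0L) floor((size - n_fibers * h) / (n_fibers + 1L)) else size
    fiber_mask <- matrix(0L, size, size)
    tops <- integer(0L)
    for (i in seq_len(n_fibers)) {
      top <- gap * i + h * (i - 1L) + 1L
      fiber_mask[top:(top + h - 1L), ] <- i
      tops <- c(tops, top)
    }
    n_fused <- round(fused_fraction * n_nuclei)
    margin <- 3L
    in_rows <- which(apply(fiber_mask > 0L, 1L, all))
    in_rows <- in_rows[in_rows %in% setdiff(in_rows,
                                            c(tops, tops + h - 1L,
                                              tops + 1L, tops + h - 2L))]
    out_rows <- setdiff(seq_len(size), which(apply(fiber_mask > 0L, 1L, any)))
    out_rows <- out_rows[vapply(out_rows, function(r) {
      all(abs(r - c(tops, tops + h - 1L)) > margin)
    }, logical(1L))]
    if (n_fibers > 0L && n_fused > 0L && length(in_rows) == 0L) {
      stop_myoquant("fibers too thin to hold nucleus centers.",
                    "myoquant_placement_error")
    }
    if (n_fused < n_nuclei && length(out_rows) == 0L) {
      stop_myoquant("no room outside fibers for unfused nuclei.",
                    "myoquant_placement_error")
    }
    centers <- matrix(NA_real_, 0L, 2L)
    radii <- numeric(0L)
    fused <- logical(0L)
    place_one <- function(target_fused, touch_partner = NULL) {
      for (try in seq_len(3000L)) {
        r <- runif(1, radius_range[1L], radius_range[2L])
        if (!is.null(touch_partner)) {
          ang <- runif(1, 0, 2 * pi)
          dist <- radii[touch_partner] + r - 1  # slight overlap: one component
          row <- centers[touch_partner, 1L] + dist * sin(ang)
          col <- centers[touch_partner, 2L] + dist * cos(ang)
          row_i <- round(row)
          ok_zone <- if (target_fused) {
            round(row) %in% in_rows
          } else {
            round(row) %in% out_rows
          }
        } else {
          row <- if (target_fused) sample(in_rows, 1L) else sample(out_rows, 1L)
          col <- runif(1, r + 2, size - r - 2)
          ok_zone <- TRUE
        }
        if (!ok_zone || col < r + 2 || col > size - r - 2 ||
            row < r + 2 || row > size - r - 2) next
        if (nrow(centers) > 0L) {
          d <- sqrt((centers[, 1L] - row)^2 + (centers[, 2L] - col)^2)
          min_sep <- radii + r + 2
          if (!is.null(touch_partner)) min_sep[touch_partner] <- 0
          if (any(d < min_sep)) next
        }
        centers <<- rbind(centers, c(row, col))
        radii <<- c(radii, r)
        fused <<- c(fused, target_fused)
        return(invisible(TRUE))
      }
      stop_myoquant("could not place a nucleus after bounded retries.",
                    "myoquant_placement_error")
    }
    n_single <- n_nuclei - 2L * n_touching_pairs
    n_fused_left <- n_fused
    for (i in seq_len(n_single)) {
      want_fused <- n_fused_left > 0L &&
        (n_single - i + 1L <= n_fused_left || runif(1) < n_fused / n_nuclei)
      if (want_fused) n_fused_left <- n_fused_left - 1L
      place_one(want_fused)
    }
    for (p in seq_len(n_touching_pairs)) {
      want_fused <- n_fused_left >= 2L
      place_one(want_fused)
      place_one(want_fused, touch_partner = nrow(centers))
      if (want_fused) n_fused_left <- n_fused_left - 2L
    }
    rows_m <- matrix(seq_len(size), size, size)
    cols_m <- t(rows_m)
    dapi <- matrix(background, size, size)
    for (i in seq_len(nrow(centers))) {
      disk <- (rows_m - centers[i, 1L])^2 + (cols_m - centers[i, 2L])^2 <=
        radii[i]^2
      dapi[disk] <- nucleus_intensity
    }
    mhc <- matrix(background, size, size)
    mhc[fiber_mask > 0L] <- fiber_intensity
    if (noise_sd > 0) {
      dapi <- pmax(dapi + matrix(rnorm(size^2, sd = noise_sd), size, size), 0)
      mhc <- pmax(mhc + matrix(rnorm(size^2, sd = noise_sd), size, size), 0)
    }
    field <- new_field(list(DAPI = dapi, MHC = mhc),
                       pixel_size_um = pixel_size_um,
                       meta = list(generator = "sim_myotube_field", seed = seed))
    truth <- new_ground_truth(
      "sim_myotube_field", seed,
      params = list(size = size, n_fibers = n_fibers, n_nuclei = n_nuclei,
                    fused_fraction = fused_fraction,
                    radius_range = radius_range,
                    n_touching_pairs = n_touching_pairs,
                    noise_sd = noise_sd),
      centers = tibble(row = centers[, 1L], col = centers[, 2L],
                       radius = radii, fused = fused),
      fiber_mask = fiber_mask > 0L,
      n_fibers = n_fibers,
      n_fused = n_fused,
      fused_fraction = fused_fraction,
      channel_sums = vapply(field$channels, sum, double(1L)))
    list(field = field, truth = truth)
  })
}

#' Generate tabular bench data (growth, Ct, MRM, MTT)
#'
#' @name sim_tabular
NULL

#' @describeIn sim_tabular Exponential growth counts with multiplicative
#'   lognormal noise of coefficient of variation `cv` (mean-one).
#' @param doubling_time_hr True doubling time.
#' @param n0 Count at time zero.
#' @param times_hr Sampling times (must start at 0).
#' @param cv Noise coefficient of variation (0 = exact).
#' @param seed RNG seed.
#' @return `sim_growth_curve()`: list with `data` tibble (`time_hr`,
#'   `count`) and `truth`.
#' @export
sim_growth_curve <- function(doubling_time_hr = 24, n0 = 1e4,
                             times_hr = c(0, 24, 48, 72), cv = 0, seed = 1L) {
  stopifnot(doubling_time_hr > 0, n0 > 0, times_hr[1L] == 0)
  withr::with_seed(as.integer(seed), {
    expected <- n0 * 2^(times_hr / doubling_time_hr)
    counts <- if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      expected * exp(rnorm(length(times_hr), -sdlog^2 / 2, sdlog))
    } else expected
    list(data = tibble(time_hr = times_hr, count = counts),
         truth = new_ground_truth("sim_growth_curve", seed,
                                  params = list(doubling_time_hr = doubling_time_hr,
                                                n0 = n0, cv = cv),
                                  doubling_time_hr = doubling_time_hr))
  })
}

#' @describeIn sim_tabular Ct table: the reference gene draws
#'   `Normal(ref_ct_mean, ref_ct_sd)` per sample; each target gene's Ct is
#'   the sample's reference Ct plus a gene offset minus `log2(fold)` for
#'   that condition, plus optional technical noise.
#' @param folds Tibble (`condition`, `gene`, `fold`) of true fold changes
#'   versus the control; the control's folds are forced to 1.
#' @param control_condition,reference_gene Table annotations.
#' @param n_replicates Samples per condition.
#' @param ref_ct_mean,ref_ct_sd Reference-gene Ct distribution.
#' @param ct_noise_sd Technical noise on target Ct values (0 = exact).
#' @return `sim_ct_table()`: list with `data` Ct tibble and `truth`
#'   (includes `folds`).
#' @export
sim_ct_table <- function(folds, control_condition = "DMSO",
                         reference_gene = "Rn18s", n_replicates = 3L,
                         ref_ct_mean = 10, ref_ct_sd = 0.3,
                         ct_noise_sd = 0, seed = 1L) {
  folds <- as_tibble(folds)
  stopifnot(all(c("condition", "gene", "fold") %in% names(folds)),
            all(folds$fold > 0))
  folds$fold[folds$condition == control_condition] <- 1
  conditions <- unique(c(control_condition, folds$condition))
  genes <- unique(folds$gene)
  withr::with_seed(as.integer(seed), {
    offsets <- setNames(runif(length(genes), 5, 15), genes)
    rows <- list()
    for (cond in conditions) {
      for (rep_i in seq_len(n_replicates)) {
        sid <- sprintf("%s_rep%d", cond, rep_i)
        ref_ct <- rnorm(1, ref_ct_mean, ref_ct_sd)
        rows[[length(rows) + 1L]] <-
          tibble(sample_id = sid, condition = cond, gene = reference_gene,
                 ct = ref_ct)
        for (gn in genes) {
          fold <- folds$fold[folds$condition == cond & folds$gene == gn]
          if (length(fold) == 0L) fold <- 1
          ct <- ref_ct + offsets[[gn]] - log2(fold) +
            (if (ct_noise_sd > 0) rnorm(1, 0, ct_noise_sd) else 0)
          rows[[length(rows) + 1L]] <-
            tibble(sample_id = sid, condition = cond, gene = gn, ct = ct)
        }
      }
    }
    list(data = bind_rows(rows),
         truth = new_ground_truth("sim_ct_table", seed,
                                  params = list(control_condition = control_condition,
                                                reference_gene = reference_gene,
                                                n_replicates = n_replicates,
                                                ct_noise_sd = ct_noise_sd),
                                  folds = folds))
  })
}

#' @describeIn sim_tabular MRM run: standard areas lie on
#'   `area = slope * conc + intercept` with relative Gaussian noise
#'   `area_cv`; sample areas are generated from true concentrations the
#'   same way.
#' @param slope,intercept True standard-curve parameters.
#' @param standards_nM Standard concentrations (default 100-500 nM).
#' @param sample_concs_nM Named numeric vector of true sample
#'   concentrations.
#' @param area_cv Relative area noise (0 = exact).
#' @param n_cells Cells per sample (scalar or named like
#'   `sample_concs_nM`).
#' @return `sim_mrm_run()`: list with `standards` tibble (`conc_nM`,
#'   `area`), `samples` tibble (`sample_id`, `area`, `n_cells`,
#'   `transition`), and `truth`.
#' @export
sim_mrm_run <- function(slope = 60, intercept = 500,
                        standards_nM = c(100, 200, 300, 400, 500),
                        sample_concs_nM = c(sample_1 = 250),
                        area_cv = 0, n_cells = 1e6, seed = 1L) {
  stopifnot(slope != 0, all(standards_nM > 0), all(sample_concs_nM >= 0))
  withr::with_seed(as.integer(seed), {
    noisy_area <- function(conc) {
      mu <- slope * conc + intercept
      if (area_cv > 0) mu * (1 + rnorm(length(mu), 0, area_cv)) else mu
    }
    standards <- tibble(conc_nM = standards_nM, area = noisy_area(standards_nM))
    cells <- if (length(n_cells) == 1L) {
      rep(n_cells, length(sample_concs_nM))
    } else n_cells[names(sample_concs_nM)]
    samples <- tibble(sample_id = names(sample_concs_nM),
                      area = noisy_area(unname(sample_concs_nM)),
                      n_cells = unname(cells),
                      transition = MRM_TRANSITIONS_15D_PGJ2[["quantifier"]])
    list(standards = standards, samples = samples,
         truth = new_ground_truth("sim_mrm_run", seed,
                                  params = list(slope = slope,
                                                intercept = intercept,
                                                area_cv = area_cv),
                                  concentrations_nM = sample_concs_nM))
  })
}

#' @describeIn sim_tabular MTT plate: replicate absorbances around
#'   per-condition means with relative Gaussian noise `cv`.
#' @param condition_means Named numeric vector of mean 570 nm absorbances.
#' @return `sim_mtt_plate()`: list with `data` tibble (`condition`,
#'   `replicate`, `abs570`) and `truth`.
#' @export
sim_mtt_plate <- function(condition_means = c(DMSO = 1.0, PGJ2 = 0.6),
                          n_replicates = 6L, cv = 0.05, seed = 1L) {
  stopifnot(all(condition_means > 0))
  withr::with_seed(as.integer(seed), {
    rows <- purrr::imap(condition_means, function(mu, cond) {
      tibble(condition = cond, replicate = seq_len(n_replicates),
             abs570 = if (cv > 0) mu * (1 + rnorm(n_replicates, 0, cv)) else
               rep(mu, n_replicates))
    })
    list(data = bind_rows(rows),
         truth = new_ground_truth("sim_mtt_plate", seed,
                                  params = list(cv = cv),
                                  condition_means = condition_means))
  })
}
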
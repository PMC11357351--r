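# Reproducible runs from a declarative config: one entry point dispatching
# the stage commands, validating everything up front (every problem is
# reported, not just the first), and writing a manifest beside the results.

#' Run a pipeline stage from a config
#'
#' The config (YAML path or list) names a `command`, a `seed`, stage
#' `params`, `inputs` (paths or condition -> file-group maps) and an output
#' directory `out`. All referenced paths are validated before anything
#' runs; validation failures enumerate every problem. A `manifest.json`
#' (command, parameters, seed, package version, per-stage record counts)
#' and a resolved copy of the config are written next to the results.
#' Payload files carry no timestamps, so identical config + seed reproduces
#' them byte-identically.
#'
#' Commands: `synth-localization`, `synth-fret`, `synth-myotube`,
#' `synth-growth`, `synth-ct`, `synth-mrm`, `rmean`, `fret-calibrate`,
#' `fret-measure`, `fusion`, `ddct`, `growth`, `lipid-quant`, `mtt`.
#'
#' @param config YAML file path or a list.
#' @return Invisibly, a list with `out` (output dir) and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop_myoquant(sprintf("config file not found: %s", config),
                    "myoquant_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  problems <- character(0)
  if (is.null(config$command)) problems <- c(problems, "missing `command`.")
  commands <- c("synth-localization", "synth-fret", "synth-myotube",
                "synth-growth", "synth-ct", "synth-mrm",
                "rmean", "fret-calibrate", "fret-measure", "fusion",
                "ddct", "growth", "lipid-quant", "mtt")
  if (!is.null(config$command) && !config$command %in% commands) {
    problems <- c(problems, sprintf("unknown command '%s' (known: %s).",
                                    config$command,
                                    paste(commands, collapse = ", ")))
  }
  if (is.null(config$out)) problems <- c(problems, "missing `out` directory.")
  for (p in unlist(config$inputs, use.names = FALSE)) {
    if (is.character(p) && !file.exists(p)) {
      problems <- c(problems, sprintf("input path not found: %s", p))
    }
  }
  seed <- config$seed %||% 1L
  if (!is.numeric(seed) || length(seed) != 1L) {
    problems <- c(problems, "`seed` must be a single number.")
  }
  if (length(problems)) {
    stop_myoquant(paste0("invalid config:\n", paste("-", problems, collapse = "\n")),
                  "myoquant_config_error")
  }
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  params <- config$params %||% list()
  counts <- dispatch_command(config$command, params, config$inputs, out,
                             as.integer(seed))
  manifest <- list(command = config$command,
                   seed = as.integer(seed),
                   params = params,
                   inputs = config$inputs,
                   package = "myoquant",
                   version = as.character(utils::packageVersion("myoquant")),
                   records = counts)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(config, file.path(out, "config_resolved.yaml"))
  invisible(list(out = out, manifest = manifest))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

dispatch_command <- function(command, params, inputs, out, seed) {
  switch(
    command,
    "synth-localization" = {
      n_fields <- params$n_fields %||% 1L
      for (i in seq_len(n_fields)) {
        sim <- do.call(sim_localization_field,
                       c(drop_keys(params, "n_fields"), list(seed = seed + i - 1L)))
        base <- file.path(out, sprintf("localization_%03d", i))
        write_field(sim$field, paste0(base, ".tif"))
        write_ground_truth(sim$truth, paste0(base, "_truth.json"))
      }
      list(fields = n_fields)
    },
    "synth-myotube" = {
      n_fields <- params$n_fields %||% 1L
      for (i in seq_len(n_fields)) {
        sim <- do.call(sim_myotube_field,
                       c(drop_keys(params, "n_fields"), list(seed = seed + i - 1L)))
        base <- file.path(out, sprintf("myotube_%03d", i))
        write_field(sim$field, paste0(base, ".tif"))
        truth <- sim$truth
        truth$centers <- as.list(truth$centers)  # tibble -> columns for JSON
        write_ground_truth(truth, paste0(base, "_truth.json"))
      }
      list(fields = n_fields)
    },
    "synth-fret" = {
      sim <- do.call(sim_fret_set, c(params, list(seed = seed)))
      write_set <- function(fields, prefix) {
        for (i in seq_along(fields)) {
          write_field(fields[[i]],
                      file.path(out, sprintf("%s_%03d.tif", prefix, i)))
        }
      }
      write_set(sim$donor_only, "donor_only")
      write_set(sim$acceptor_only, "acceptor_only")
      write_set(sim$experimental, "experimental")
      truth <- sim$truth; truth$cell_masks <- NULL
      write_ground_truth(truth, file.path(out, "fret_truth.json"))
      list(donor_only = length(sim$donor_only),
           acceptor_only = length(sim$acceptor_only),
           experimental = length(sim$experimental))
    },
    "synth-growth" = {
      sim <- do.call(sim_growth_curve, c(params, list(seed = seed)))
      readr::write_csv(sim$data, file.path(out, "growth.csv"))
      write_ground_truth(sim$truth, file.path(out, "growth_truth.json"))
      list(rows = nrow(sim$data))
    },
    "synth-ct" = {
      folds <- as_tibble(params$folds)
      sim <- do.call(sim_ct_table,
                     c(list(folds = folds), drop_keys(params, "folds"),
                       list(seed = seed)))
      readr::write_csv(sim$data, file.path(out, "ct.csv"))
      truth <- sim$truth; truth$folds <- as.list(truth$folds)
      write_ground_truth(truth, file.path(out, "ct_truth.json"))
      list(rows = nrow(sim$data))
    },
    "synth-mrm" = {
      p <- params
      if (!is.null(p$sample_concs_nM)) p$sample_concs_nM <- unlist(p$sample_concs_nM)
      sim <- do.call(sim_mrm_run, c(p, list(seed = seed)))
      readr::write_csv(sim$standards, file.path(out, "standards.csv"))
      readr::write_csv(sim$samples, file.path(out, "samples.csv"))
      write_ground_truth(sim$truth, file.path(out, "mrm_truth.json"))
      list(standards = nrow(sim$standards), samples = nrow(sim$samples))
    },
    "rmean" = {
      groups <- inputs  # condition -> vector of multipage tiffs
      fields <- list(); conditions <- character(0)
      for (cond in names(groups)) {
        for (path in groups[[cond]]) {
          fields[[length(fields) + 1L]] <-
            read_field(file = path, roles = c("HRAS_EGFP", "GOLGI_RFP", "PM_WGA"))
          names(fields)[length(fields)] <-
            tools::file_path_sans_ext(basename(path))
          conditions <- c(conditions, cond)
        }
      }
      batch <- batch_rmean(fields, conditions,
                           control = params$control %||% names(groups)[[1L]])
      readr::write_csv(batch$per_field, file.path(out, "rmean.csv"))
      readr::write_csv(batch$summary, file.path(out, "rmean_summary.csv"))
      list(fields = nrow(batch$per_field), excluded = nrow(batch$excluded))
    },
    "fret-calibrate" = {
      read_set <- function(paths) lapply(paths, function(p)
        read_field(file = p, roles = c("DONOR", "ACCEPTOR", "FRET")))
      coeffs <- estimate_bleedthrough(read_set(inputs$donor_only),
                                      read_set(inputs$acceptor_only))
      write_bleedthrough(coeffs, file.path(out, "coeffs.json"))
      list(n_px_donor = coeffs$n_px_donor, n_px_acceptor = coeffs$n_px_acceptor)
    },
    "fret-measure" = {
      coeffs <- read_bleedthrough(inputs$coeffs)
      measure <- function(paths) bind_rows(lapply(paths, function(p) {
        f <- read_field(file = p, roles = c("DONOR", "ACCEPTOR", "FRET"))
        compute_fret_index(f, coeffs,
                           field_id = tools::file_path_sans_ext(basename(p)))
      }))
      pre <- measure(inputs$pre)
      post <- measure(inputs$post)
      readr::write_csv(bind_rows(mutate(pre, phase = "pre"),
                                 mutate(post, phase = "post")),
                       file.path(out, "fret.csv"))
      readr::write_csv(fret_paired_change(pre, post),
                       file.path(out, "fret_change.csv"))
      list(pairs = nrow(pre))
    },
    "fusion" = {
      rows <- list(); per_fiber <- list()
      for (path in unlist(inputs, use.names = FALSE)) {
        f <- read_field(file = path, roles = c("DAPI", "MHC"))
        id <- tools::file_path_sans_ext(basename(path))
        nuclei <- segment_nuclei(f, min_area = params$min_area %||% 30L,
                                 split_touching = isTRUE(params$split_touching))
        fibers <- segment_fibers(f, min_area = params$fiber_min_area %||% 200L)
        fr <- fusion_index(nuclei, fibers)
        rows[[id]] <- mutate(fr$summary, field_id = id, .before = 1L)
        if (nrow(fr$per_fiber)) {
          per_fiber[[id]] <- mutate(fr$per_fiber, field_id = id, .before = 1L)
        }
      }
      readr::write_csv(bind_rows(rows), file.path(out, "fusion.csv"))
      readr::write_csv(bind_rows(per_fiber), file.path(out, "nuclei_per_fiber.csv"))
      list(fields = length(rows))
    },
    "ddct" = {
      ct <- readr::read_csv(inputs$ct, show_col_types = FALSE)
      res <- relative_expression(ct,
                                 reference_gene = params$reference_gene,
                                 control_condition = params$control_condition,
                                 mode = params$mode %||% "ddct")
      readr::write_csv(res, file.path(out, "relative_expression.csv"))
      list(rows = nrow(res))
    },
    "growth" = {
      counts <- readr::read_csv(inputs$counts, show_col_types = FALSE)
      res <- doubling_time(counts)
      readr::write_csv(res, file.path(out, "doubling_time.csv"))
      list(rows = nrow(res))
    },
    "lipid-quant" = {
      standards <- readr::read_csv(inputs$standards, show_col_types = FALSE)
      samples <- readr::read_csv(inputs$samples, show_col_types = FALSE)
      curve <- fit_standard_curve(standards)
      res <- quantify_lipid(samples, curve,
                            resuspension_volume_uL =
                              params$resuspension_volume_uL %||% 100,
                            medium_volume_mL = params$medium_volume_mL %||% 1.35)
      readr::write_csv(res, file.path(out, "lipid_quant.csv"))
      readr::write_csv(glance(curve), file.path(out, "standard_curve.csv"))
      list(samples = nrow(res))
    },
    "mtt" = {
      plate <- readr::read_csv(inputs$plate, show_col_types = FALSE)
      res <- mtt_viability(plate, control = params$control)
      readr::write_csv(res, file.path(out, "mtt.csv"))
      list(rows = nrow(res))
    }
  )
}

drop_keys <- function(x, keys) x[setdiff(names(x), keys)]
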
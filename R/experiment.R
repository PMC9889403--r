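#' Parse and validate an experiment configuration
#'
#' Reads a flat YAML/JSON configuration (or takes an equivalent named
#' list), applies defaults, and checks every invariant, reporting all
#' violations at once. Recognized keys: `experiment` (one of
#' `dose_response`, `activation_sweep`, `feedback_sweep`,
#' `logic_compare`, `cascade_compare`), the kinetic parameter symbols of
#' [kinetic_parameters()], `kinetics`, `feedback_logic`, `hill_K`,
#' `hill_n`, `seed`, `n` (sample count), `n_doses`, `S_min`, `S_max`,
#' `sweep_name`, `sweep_lo`, `sweep_hi`, `sweep_n`, `trend_tolerance`.
#'
#' @param raw path to a YAML/JSON file, or a named list.
#' @return An object of class `experiment_config` echoing all defaults.
#' @export
validate_config <- function(raw) {
  cfg <- if (is.character(raw) && length(raw) == 1L) {
    read_flat_config(raw)
  } else if (is.list(raw)) {
    raw
  } else {
    stop("config must be a file path or a named list")
  }
  errors <- character(0)
  note <- function(msg) errors <<- c(errors, msg)

  experiments <- c("dose_response", "activation_sweep", "feedback_sweep",
                   "logic_compare", "cascade_compare")
  if (is.null(cfg$experiment) || !cfg$experiment %in% experiments) {
    note(paste0("`experiment` must be one of: ",
                paste(experiments, collapse = ", ")))
  }
  kin <- cfg$kinetics %||% "mass_action"
  if (!kin %in% c("mass_action", "hill")) {
    note("`kinetics` must be 'mass_action' or 'hill'")
  }
  logic <- cfg$feedback_logic %||% "none"
  if (!logic %in% c("none", "and", "or")) {
    note("`feedback_logic` must be 'none', 'and' or 'or'")
  }
  if (identical(kin, "hill") &&
      (is.null(cfg$hill_K) || is.null(cfg$hill_n))) {
    warning("hill kinetics without explicit hill_K/hill_n; defaults applied",
            call. = FALSE)
  }
  par_args <- cfg[intersect(.param_fields, names(cfg))]
  params <- tryCatch(do.call(kinetic_parameters, par_args),
                     error = function(e) {
                       note(conditionMessage(e))
                       NULL
                     })
  hill <- tryCatch(hill_spec(K = cfg$hill_K %||% 0.5,
                             n = cfg$hill_n %||% 1.5),
                   error = function(e) { note(conditionMessage(e)); NULL })
  for (nm in c("seed", "n", "n_doses", "sweep_n")) {
    if (!is.null(cfg[[nm]]) &&
        (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 0 ||
         cfg[[nm]] != round(cfg[[nm]]))) {
      note(paste0("`", nm, "` must be a nonnegative integer"))
    }
  }
  S_min <- cfg$S_min %||% 1e-5
  S_max <- cfg$S_max %||% 1e3
  if (!is.numeric(S_min) || !is.numeric(S_max) || S_min <= 0 ||
      S_max <= S_min) {
    note("dose range must satisfy 0 < S_min < S_max")
  }
  if (identical(cfg$experiment, "activation_sweep")) {
    if (is.null(cfg$sweep_name) || !cfg$sweep_name %in% .param_fields) {
      note("activation_sweep needs `sweep_name`, a kinetic parameter symbol")
    }
    lo <- cfg$sweep_lo; hi <- cfg$sweep_hi
    if (is.null(lo) || is.null(hi) || !is.numeric(lo) || !is.numeric(hi) ||
        lo <= 0 || hi <= lo) {
      note("activation_sweep needs 0 < sweep_lo < sweep_hi")
    }
  }
  if (length(errors) > 0L) {
    stop("invalid experiment config:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  }
  structure(list(
    experiment = cfg$experiment,
    params = params,
    spec = model_spec(kin, logic, hill),
    seed = as.integer(cfg$seed %||% 1L),
    n = as.integer(cfg$n %||% 100L),
    n_doses = as.integer(cfg$n_doses %||% 60L),
    S_min = S_min, S_max = S_max,
    sweep_name = cfg$sweep_name %||% NA_character_,
    sweep_lo = cfg$sweep_lo %||% NA_real_,
    sweep_hi = cfg$sweep_hi %||% NA_real_,
    sweep_n = as.integer(cfg$sweep_n %||% 9L),
    trend_tolerance = cfg$trend_tolerance %||% 0.01
  ), class = "experiment_config")
}

#' Serialize an experiment configuration back to a flat list
#'
#' Inverse of [validate_config()] up to default filling: the returned
#' flat list parses back to an identical `experiment_config`.
#'
#' @param cfg an `experiment_config`.
#' @return Flat named list.
#' @export
config_to_list <- function(cfg) {
  c(list(experiment = cfg$experiment),
    model_to_config(cfg$params, cfg$spec),
    list(seed = cfg$seed, n = cfg$n, n_doses = cfg$n_doses,
         S_min = cfg$S_min, S_max = cfg$S_max,
         sweep_name = cfg$sweep_name, sweep_lo = cfg$sweep_lo,
         sweep_hi = cfg$sweep_hi, sweep_n = cfg$sweep_n,
         trend_tolerance = cfg$trend_tolerance))
}

#' Run one configured experiment
#'
#' Executes the pipeline stage named in the config and writes its outputs
#' under `out_dir`: a tidy CSV of results, a JSON summary (numbers
#' rounded to 6 significant digits, as noted in the file), a verbatim
#' copy of the parsed config, a plain-text log, and a manifest listing
#' every output with its MD5 content hash. All randomness flows from the
#' config seed, so identical configs give identical content hashes.
#'
#' @param cfg an `experiment_config` from [validate_config()], or a path
#'   or list accepted by it.
#' @param out_dir output directory (created if missing).
#' @return List with `status` (`"ok"` or `"partial"` if any per-point
#'   solve failed), `summary`, and `files` (the manifest data frame),
#'   invisibly.
#' @export
run_experiment <- function(cfg, out_dir) {
  if (!inherits(cfg, "experiment_config")) cfg <- validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  S_grid <- default_dose_grid(cfg$n_doses, cfg$S_min, cfg$S_max)
  log("experiment: ", cfg$experiment)
  log("variant: ", cfg$spec$kinetics, " / ", cfg$spec$feedback_logic)
  log("seed: ", cfg$seed, "  n: ", cfg$n, "  doses: ", cfg$n_doses,
      " on [", cfg$S_min, ", ", cfg$S_max, "]")

  res <- switch(cfg$experiment,
    dose_response = {
      drc <- dose_response(cfg$params, cfg$spec, S_grid)
      norm <- normalize_curves(drc)
      list(table = drc$curve,
           summary = list(R_max = drc$R_max, mG_max = drc$mG_max,
                          tG_max = drc$tG_max,
                          metric_mG = dora_metric(norm, "mG"),
                          metric_tG = dora_metric(norm, "tG")),
           n_failed = 0L)
    },
    activation_sweep = {
      values <- 10^seq(log10(cfg$sweep_lo), log10(cfg$sweep_hi),
                       length.out = max(cfg$sweep_n, 2L))
      tab <- sweep_single_parameter(cfg$sweep_name, values, cfg$params,
                                    cfg$spec, S_grid)
      tr <- classify_trend(tab$metric_mG, cfg$trend_tolerance)
      list(table = tab,
           summary = list(swept = cfg$sweep_name,
                          trend_metric_mG = tr$label,
                          trend_ambiguous = tr$ambiguous),
           n_failed = sum(!is.na(tab$error)))
    },
    feedback_sweep = {
      sets <- sample_parameter_space(cfg$n, cfg$spec, seed = cfg$seed,
                                     base = cfg$params)
      kg <- feedback_grid(cfg$sweep_n)
      rows <- lapply(seq_along(sets), function(i) {
        tab <- sweep_single_parameter("k_feedback", kg, sets[[i]],
                                      cfg$spec, S_grid)
        tr <- classify_trend(tab$metric_mG, cfg$trend_tolerance)
        data.frame(set = i,
                   mG_activation_no_fb = tab$mG_activation[1],
                   trend = tr$label,
                   ambiguous = tr$ambiguous,
                   n_failed = sum(!is.na(tab$error)))
      })
      tab <- do.call(rbind, rows)
      counts <- table(factor(tab$trend,
                             levels = c("increasing", "decreasing",
                                        "dec_then_inc", "inc_then_dec",
                                        "flat")))
      list(table = tab,
           summary = c(as.list(counts),
                       list(n_sets = cfg$n, n_ambiguous = sum(tab$ambiguous))),
           n_failed = sum(tab$n_failed))
    },
    logic_compare = {
      sets <- sample_parameter_space(cfg$n, cfg$spec, seed = cfg$seed,
                                     base = cfg$params)
      rng <- local_rng(cfg$seed + 1L)
      k_and <- 10^stats::runif(length(sets), log10(1e-2), 2.6)
      rng$restore()
      cmp <- compare_logic_gates(sets, k_and, cfg$spec, S_grid)
      list(table = cmp$pairs,
           summary = list(
             mean_diagonal_distance = cmp$mean_diagonal_distance,
             n_pairs = nrow(cmp$pairs),
             n_failed = sum(!is.na(cmp$pairs$error))),
           n_failed = sum(!is.na(cmp$pairs$error)))
    },
    cascade_compare = {
      sets <- sample_parameter_space(cfg$n, cfg$spec, seed = cfg$seed,
                                     base = cfg$params)
      rows <- lapply(seq_along(sets), function(i) {
        tryCatch(evaluate_dora(sets[[i]], cfg$spec, S_grid,
                               params_id = as.character(i)),
                 error = function(e) data.frame(
                   params_id = as.character(i), metric_mG = NA_real_,
                   metric_tG = NA_real_, mG_activation = NA_real_))
      })
      tab <- do.call(rbind, rows)
      cc <- compare_cascade(tab)
      list(table = tab,
           summary = list(n_above = cc$n_above, n_below = cc$n_below,
                          n_on = cc$n_on,
                          min_metric_mG = cc$min_metric_mG,
                          min_metric_tG = cc$min_metric_tG),
           n_failed = sum(is.na(tab$metric_mG)))
    }
  )

  results_csv <- file.path(out_dir, "results.csv")
  utils::write.csv(res$table, results_csv, row.names = FALSE)
  summary_json <- file.path(out_dir, "summary.json")
  jsonlite::write_json(
    c(res$summary, list(precision_note = "6 significant digits")),
    summary_json, auto_unbox = TRUE, digits = 6)
  config_json <- file.path(out_dir, "config.json")
  jsonlite::write_json(config_to_list(cfg), config_json,
                       auto_unbox = TRUE, digits = NA)
  log("points failed: ", res$n_failed)
  log_file <- file.path(out_dir, "run.log")
  writeLines(log_lines, log_file)
  files <- c(results_csv, summary_json, config_json, log_file)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(list(status = if (res$n_failed > 0) "partial" else "ok",
                 summary = res$summary, files = manifest))
}
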
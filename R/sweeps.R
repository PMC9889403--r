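#' Evaluate the DoRA metrics for one parameter set
#'
#' Computes the dose-response curve, normalizes it, and returns the
#' distance metrics of both GTPases together with the mGTPase activation
#' level — the unit of work of every sweep pipeline.
#'
#' @inheritParams derived_constants
#' @param S_grid dose grid for the metric quadrature.
#' @param params_id optional provenance label carried into the result.
#' @return One-row data frame with `params_id`, `metric_mG`, `metric_tG`,
#'   `mG_activation`.
#' @export
evaluate_dora <- function(params, spec, S_grid = default_dose_grid(),
                          params_id = NA_character_) {
  drc <- dose_response(params, spec, S_grid)
  norm <- normalize_curves(drc)
  data.frame(
    params_id = params_id,
    metric_mG = dora_metric(norm, "mG"),
    metric_tG = dora_metric(norm, "tG"),
    mG_activation = drc$mG_max,
    stringsAsFactors = FALSE
  )
}

#' Log-uniform sample of the kinetic parameter space
#'
#' Draws `n` parameter sets from the configured log-uniform ranges,
#' leaving all other rate constants at the base template values.
#' Deterministic under the supplied seed; the caller's RNG state is left
#' untouched.
#'
#' @param n number of parameter sets (0 gives an empty list).
#' @param sample_names names of the rate constants to draw; defaults to
#'   the spaces explored in the activation-level analyses
#'   (`k_on_mG`, `k_on_tG`, `k_on_mGAP` for mass action, plus `k_on_R`
#'   for Hill kinetics, whose receptor activation level is tunable).
#' @inheritParams derived_constants
#' @param seed integer seed.
#' @param base base [kinetic_parameters()] template.
#' @param ranges named list of `c(lo, hi)` ranges; see [default_ranges()].
#' @return List of [kinetic_parameters()] objects.
#' @export
sample_parameter_space <- function(n, spec = model_spec(),
                                   sample_names = NULL, seed = 1,
                                   base = default_parameters(spec),
                                   ranges = default_ranges()) {
  if (is.null(sample_names)) {
    sample_names <- c("k_on_mG", "k_on_tG", "k_on_mGAP")
    if (spec$kinetics == "hill") sample_names <- c("k_on_R", sample_names)
  }
  if (n == 0L) return(list())
  rng <- local_rng(seed)
  on.exit(rng$restore())
  lapply(seq_len(n), function(i) {
    p <- unclass(base)
    for (nm in sample_names) {
      r <- ranges[[nm]]
      if (is.null(r)) stop("no sampling range configured for ", nm)
      p[[nm]] <- 10^stats::runif(1, log10(max(r[1], 1e-12)), log10(r[2]))
    }
    do.call(kinetic_parameters, p[.param_fields])
  })
}

#' Single-parameter sweep of the DoRA metrics
#'
#' Re-evaluates the distance metrics and the mGTPase activation level
#' while one kinetic parameter steps through an ordered value grid.
#' Per-point solver failures are recorded in the `error` column rather
#' than aborting the sweep.
#'
#' @param name name of the swept kinetic parameter (e.g. `"k_on_mGAP"`,
#'   `"k_feedback"`).
#' @param values ordered numeric vector of swept values.
#' @param base base [kinetic_parameters()] template.
#' @inheritParams evaluate_dora
#' @return Data frame ordered by the swept value with columns `value`,
#'   `metric_mG`, `metric_tG`, `mG_activation`, `error`.
#' @export
sweep_single_parameter <- function(name, values, base, spec,
                                   S_grid = default_dose_grid()) {
  if (!name %in% .param_fields) stop("unknown kinetic parameter: ", name)
  rows <- lapply(values, function(v) {
    p <- unclass(base)
    p[[name]] <- v
    tryCatch({
      p <- do.call(kinetic_parameters, p[.param_fields])
      r <- evaluate_dora(p, spec, S_grid)
      data.frame(value = v, metric_mG = r$metric_mG,
                 metric_tG = r$metric_tG,
                 mG_activation = r$mG_activation, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(value = v, metric_mG = NA_real_, metric_tG = NA_real_,
                 mG_activation = NA_real_, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}

#' Default feedback-strength grid
#'
#' Zero (the no-feedback degenerate point) followed by log-spaced values
#' up to `10^2.6`, the upper end of the explored feedback range.
#'
#' @param n total number of points including zero (at least 9 by default).
#' @param lo smallest nonzero strength.
#' @param hi largest strength.
#' @return Ordered numeric vector starting at 0.
#' @export
feedback_grid <- function(n = 9, lo = 1e-1, hi = 10^2.6) {
  c(0, 10^seq(log10(lo), log10(hi), length.out = n - 1))
}

#' Classify the trend of an ordered value sequence
#'
#' Labels the sign pattern of successive differences after discarding
#' steps smaller than a relative tolerance: monotone patterns map to
#' `"increasing"` / `"decreasing"`, one sign change to
#' `"dec_then_inc"` / `"inc_then_dec"`, and no surviving steps to
#' `"flat"`. Sequences with two or more sign changes are flagged as
#' ambiguous (label `NA`) for manual review.
#'
#' @param values ordered numeric vector (length at least 2).
#' @param tolerance relative change below which a step counts as flat
#'   (default 1%).
#' @return List with `label` and logical `ambiguous`.
#' @examples
#' classify_trend(c(3, 2, 1))$label        # "decreasing"
#' classify_trend(c(1, 0.5, 0.8))$label    # "dec_then_inc"
#' @export
classify_trend <- function(values, tolerance = 0.01) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) {
    if (length(values) == 1L) {
      return(list(label = "flat", ambiguous = FALSE))
    }
    stop("need at least 2 values to classify a trend")
  }
  scale <- pmax(abs(values[-length(values)]), abs(values[-1]),
                .Machine$double.eps)
  d <- diff(values)
  signs <- sign(d)[abs(d) / scale > tolerance]
  if (length(signs) == 0L) return(list(label = "flat", ambiguous = FALSE))
  runs <- rle(signs)$values
  label <- if (length(runs) == 1L) {
    if (runs == 1) "increasing" else "decreasing"
  } else if (length(runs) == 2L) {
    if (runs[1] == -1) "dec_then_inc" else "inc_then_dec"
  } else {
    NA_character_
  }
  list(label = label, ambiguous = is.na(label))
}

#' Binned mean and spread of a metric against the activation level
#'
#' Equal-width bins on `mG_activation`; empty bins are omitted and
#' flagged in the `empty_bins` attribute.
#'
#' @param results data frame with columns `mG_activation` and the metric.
#' @param n_bins number of equal-width bins.
#' @param metric_col name of the metric column (default `"metric_mG"`).
#' @return Data frame with `bin_mid`, `n`, `mean`, `sd` per occupied bin.
#' @export
binned_mean_metric <- function(results, n_bins = 10,
                               metric_col = "metric_mG") {
  act <- results$mG_activation
  met <- results[[metric_col]]
  keep <- !is.na(act) & !is.na(met)
  act <- act[keep]; met <- met[keep]
  breaks <- seq(min(act), max(act), length.out = n_bins + 1)
  breaks[1] <- breaks[1] - 1e-12
  idx <- cut(act, breaks, labels = FALSE)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  occupied <- sort(unique(idx))
  out <- data.frame(
    bin_mid = mids[occupied],
    n = vapply(occupied, function(b) sum(idx == b), integer(1)),
    mean = vapply(occupied, function(b) mean(met[idx == b]), numeric(1)),
    sd = vapply(occupied, function(b) stats::sd(met[idx == b]), numeric(1))
  )
  attr(out, "empty_bins") <- setdiff(seq_len(n_bins), occupied)
  out
}

#' Feedback strength matching the OR gate to an AND-gate activation level
#'
#' Finds `k_feedback^OR` such that the OR-gate model reaches the same
#' mGTPase activation level as the AND-gate model with strength
#' `k_fb_and`. At the infinite-stimulus fixed point both gates must
#' produce the same mGAP level, which gives the closed-form matching
#' `k_OR = k_AND * f(tGEF_max) * f(tG*_max) / (f(tGEF_max) + f(tG*_max))`
#' (for mass action, `f` is the identity, recovering the
#' `h1 h2 / (h1 + h2)` ratio). The closed form is polished and verified by
#' bracketed root-finding on the activation-level mismatch.
#'
#' @param params base [kinetic_parameters()] (its `k_feedback` is ignored).
#' @param spec a [model_spec()]; the feedback logic field is overridden by
#'   AND/OR as needed.
#' @param k_fb_and feedback strength of the AND-gate model.
#' @param method `"root"` (default; closed form refined by root-finding)
#'   or `"closed_form"`.
#' @param tol tolerance on the activation-level match.
#' @return `k_feedback^OR` as a scalar.
#' @export
match_or_feedback_strength <- function(params, spec, k_fb_and,
                                       method = c("root", "closed_form"),
                                       tol = 1e-10) {
  method <- match.arg(method)
  if (k_fb_and == 0) return(0)
  p_and <- params; p_and$k_feedback <- k_fb_and
  spec_and <- spec; spec_and$feedback_logic <- "and"
  spec_or <- spec; spec_or$feedback_logic <- "or"
  R_max <- receptor_max(params, spec)
  st_max <- steady_state_at_receptor(R_max, p_and, spec_and)
  f1 <- kinetic_f(st_max[["tGEF"]], spec)
  f2 <- kinetic_f(st_max[["tG_star"]], spec)
  if (f1 + f2 <= 0) stop("degenerate saturation state: no feedback drive")
  k_closed <- k_fb_and * f1 * f2 / (f1 + f2)
  if (method == "closed_form") return(k_closed)
  target <- st_max[["mG_star"]]
  mismatch <- function(k) {
    p <- params; p$k_feedback <- k
    steady_state_at_receptor(R_max, p, spec_or)[["mG_star"]] - target
  }
  # activation decreases in k; bracket around the closed-form value
  lo <- k_closed / 2
  hi <- k_closed * 2
  flo <- mismatch(lo); fhi <- mismatch(hi)
  while (flo < 0 && lo > 1e-300) { lo <- lo / 4; flo <- mismatch(lo) }
  while (fhi > 0 && hi < 1e300) { hi <- hi * 4; fhi <- mismatch(hi) }
  if (flo < 0 || fhi > 0) stop("could not bracket the matched OR strength")
  stats::uniroot(mismatch, lower = lo, upper = hi, f.lower = flo,
                 f.upper = fhi, tol = tol * k_closed)$root
}

#' Matched-activation comparison of AND vs OR feedback gates
#'
#' For each sampled parameter set and AND-gate feedback strength, matches
#' the OR-gate strength via [match_or_feedback_strength()], evaluates both
#' distance metrics, and summarizes the paired scatter by the mean
#' perpendicular distance of the points to the diagonal. Per-pair solver
#' failures are logged in the result and skipped from the summary.
#'
#' @param param_sets list of [kinetic_parameters()] objects.
#' @param k_fb_and AND-gate feedback strengths, recycled to the number of
#'   parameter sets.
#' @inheritParams evaluate_dora
#' @param species `"mG"` or `"tG"`.
#' @return List with `pairs` (data frame `metric_and`, `metric_or`,
#'   `k_and`, `k_or`, `mG_activation`, `error`),
#'   `mean_diagonal_distance`, and `mean_metric_and` (the scale against
#'   which the diagonal distance is judged).
#' @export
compare_logic_gates <- function(param_sets, k_fb_and, spec,
                                S_grid = default_dose_grid(),
                                species = "mG") {
  k_fb_and <- rep_len(k_fb_and, length(param_sets))
  rows <- Map(function(p, k_and) {
    tryCatch({
      k_or <- match_or_feedback_strength(p, spec, k_and)
      p_and <- p; p_and$k_feedback <- k_and
      p_or <- p; p_or$k_feedback <- k_or
      spec_and <- spec; spec_and$feedback_logic <- "and"
      spec_or <- spec; spec_or$feedback_logic <- "or"
      n_and <- normalize_curves(dose_response(p_and, spec_and, S_grid))
      n_or <- normalize_curves(dose_response(p_or, spec_or, S_grid))
      data.frame(
        metric_and = dora_metric(n_and, species),
        metric_or = dora_metric(n_or, species),
        k_and = k_and, k_or = k_or,
        mG_activation = activation_levels(p_and, spec_and)[["mG_max"]],
        error = NA_character_, stringsAsFactors = FALSE
      )
    }, error = function(e) {
      data.frame(metric_and = NA_real_, metric_or = NA_real_,
                 k_and = k_and, k_or = NA_real_, mG_activation = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
  }, param_sets, as.list(k_fb_and))
  pairs <- do.call(rbind, rows)
  ok <- is.na(pairs$error)
  list(
    pairs = pairs,
    mean_diagonal_distance =
      mean(abs(pairs$metric_and[ok] - pairs$metric_or[ok])) / sqrt(2),
    mean_metric_and = mean(pairs$metric_and[ok])
  )
}

#' Cascade-length comparison of the paired GTPase metrics
#'
#' Summarizes a set of DoRA results as the (metric_mG, metric_tG) scatter:
#' counts of pairs above the diagonal (tGTPase worse, the mass-action
#' prediction) and strictly below it (tGTPase better), with the activation
#' levels of the below-diagonal subset.
#'
#' @param results data frame with columns `metric_mG`, `metric_tG`,
#'   `mG_activation`.
#' @param tol absolute tolerance for calling a pair on the diagonal.
#' @return List with `pairs`, `n_above`, `n_below`, `n_on`,
#'   `below_diagonal` (subset data frame), `min_metric_mG`,
#'   `min_metric_tG`.
#' @export
compare_cascade <- function(results, tol = 1e-12) {
  keep <- !is.na(results$metric_mG) & !is.na(results$metric_tG)
  r <- results[keep, , drop = FALSE]
  diffs <- r$metric_tG - r$metric_mG
  list(
    pairs = r,
    n_above = sum(diffs > tol),
    n_below = sum(diffs < -tol),
    n_on = sum(abs(diffs) <= tol),
    below_diagonal = r[diffs < -tol, , drop = FALSE],
    min_metric_mG = min(r$metric_mG),
    min_metric_tG = min(r$metric_tG)
  )
}
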
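#' Baseline kinetic parameter set per model variant
#'
#' Documented defaults used throughout the sweep pipelines: every rate
#' constant and the tGAP concentration are 1 and the feedback strength 0,
#' so that under mass action the composite `a_M = 1` and hence the
#' mGTPase activation level is exactly 0.5 (the middle of its range).
#' The same rate constants are used for the Hill variants, with the Hill
#' constants carried by the `model_spec`.
#'
#' @param spec a [model_spec()] (recorded for provenance; the baseline
#'   rates are variant-independent).
#' @return A [kinetic_parameters()] object.
#' @export
default_parameters <- function(spec = model_spec()) {
  kinetic_parameters()
}

#' Default sampling ranges of the swept rate constants
#'
#' Log-uniform sampling ranges: `[1e-2, 1e1]` for generic rate constants,
#' `[0.01, 1]` for the constitutive mGAP production rate, and
#' `[0, 10^2.6]` for the feedback strength.
#'
#' @return Named list of `c(lo, hi)` ranges.
#' @export
default_ranges <- function() {
  list(
    k_on_R = c(1e-2, 1e1),
    k_on_mG = c(1e-2, 1e1),
    k_on_tG = c(1e-2, 1e1),
    k_on_mGAP = c(0.01, 1),
    k_feedback = c(0, 10^2.6)
  )
}

#' Activation-regime preset sampler
#'
#' Rejection-samples kinetic parameter sets from the default log-uniform
#' space until the computed mGTPase activation level falls in the target
#' interval of the requested regime: high (`>= 0.8`), low (`<= 0.2`) or
#' intermediate (`[0.35, 0.65]`). Deterministic under the supplied seed.
#'
#' @param regime `"high_activation"`, `"intermediate_activation"` or
#'   `"low_activation"`.
#' @param spec a [model_spec()].
#' @param seed integer seed.
#' @param base base [kinetic_parameters()] template.
#' @param sample_names parameters drawn log-uniformly from
#'   [default_ranges()].
#' @param max_tries rejection budget before erroring.
#' @return A [kinetic_parameters()] object whose `mG_max` lies in the
#'   target interval (attached as attribute `mG_activation`).
#' @export
preset_for_regime <- function(regime = c("high_activation",
                                         "intermediate_activation",
                                         "low_activation"),
                              spec = model_spec(), seed = 1,
                              base = default_parameters(spec),
                              sample_names = c("k_on_mG", "k_on_tG",
                                               "k_on_mGAP"),
                              max_tries = 1000L) {
  regime <- match.arg(regime)
  target <- switch(regime,
    high_activation = c(0.8, 1),
    intermediate_activation = c(0.35, 0.65),
    low_activation = c(0, 0.2)
  )
  rng <- local_rng(seed)
  ranges <- default_ranges()
  for (i in seq_len(max_tries)) {
    p <- base
    for (nm in sample_names) {
      r <- ranges[[nm]]
      p[[nm]] <- 10^stats::runif(1, log10(max(r[1], 1e-12)), log10(r[2]))
    }
    p <- do.call(kinetic_parameters, p[.param_fields])
    act <- activation_levels(p, spec)[["mG_max"]]
    if (act >= target[1] && act <= target[2]) {
      rng$restore()
      attr(p, "mG_activation") <- act
      return(p)
    }
  }
  rng$restore()
  stop("no parameter set with mG activation in [", target[1], ", ",
       target[2], "] found after ", max_tries, " draws for spec ",
       spec$kinetics, "/", spec$feedback_logic)
}

# Seed the RNG locally and restore the caller's state afterwards.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  list(restore = function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
}

#' Analytic toy curves with known distance-metric values
#'
#' Closed-form normalized curves for metric unit checks, each with its
#' exact metric attached:
#' * `perfect`: `v = u` (metric 0);
#' * `saturated`: `v = 1` (metric 1/2);
#' * `michaelian`: `v = (1 + a) u / (u + a)` with metric
#'   `(1 + a) (1 - a log((1 + a)/a)) - 1/2`.
#'
#' @param a Michaelian shape constant (default 1, metric `3/2 - 2 log 2`).
#' @param n_grid number of equally spaced `u` samples on \[0, 1\].
#' @return Named list of `normalized_curves`, each carrying attribute
#'   `exact_metric`.
#' @export
toy_curve_fixtures <- function(a = 1, n_grid = 201) {
  u <- seq(0, 1, length.out = n_grid)
  fixture <- function(v, exact) {
    nc <- normalized_curves(u, v)
    attr(nc, "exact_metric") <- exact
    nc
  }
  list(
    perfect = fixture(u, 0),
    saturated = fixture(rep(1, n_grid), 0.5),
    michaelian = fixture((1 + a) * u / (u + a),
                         (1 + a) * (1 - a * log((1 + a) / a)) - 0.5)
  )
}
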
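# Shared fixtures: the six model variants and a small seeded parameter draw.

all_model_specs <- function(hill = hill_spec()) {
  list(
    ma_none = model_spec("mass_action", "none", hill),
    ma_and = model_spec("mass_action", "and", hill),
    ma_or = model_spec("mass_action", "or", hill),
    hill_none = model_spec("hill", "none", hill),
    hill_and = model_spec("hill", "and", hill),
    hill_or = model_spec("hill", "or", hill)
  )
}

# One random parameter set per seed, with a nonzero feedback strength for
# feedback variants.
random_params <- function(spec, seed, k_feedback_range = c(1e-1, 10^2.6)) {
  p <- sample_parameter_space(1, spec, seed = seed)[[1]]
  if (spec$feedback_logic != "none") {
    r <- local({
      set.seed(seed + 10000L)
      10^stats::runif(1, log10(k_feedback_range[1]),
                      log10(k_feedback_range[2]))
    })
    p$k_feedback <- r
    p <- do.call(kinetic_parameters, unclass(p))
  }
  p
}

# Evaluate a whole sampled space, recording degenerate sets (zero
# activation, unresolvable in double precision) as NA rows.
evaluate_space <- function(sets, spec) {
  rows <- lapply(seq_along(sets), function(i) {
    tryCatch(
      evaluate_dora(sets[[i]], spec, params_id = as.character(i)),
      error = function(e) data.frame(
        params_id = as.character(i), metric_mG = NA_real_,
        metric_tG = NA_real_, mG_activation = NA_real_,
        stringsAsFactors = FALSE
      )
    )
  })
  do.call(rbind, rows)
}

# Random state inside the invariant box.
random_state <- function(seed) {
  set.seed(seed)
  system_state(
    R_star = stats::runif(1), mGEF = stats::runif(1, 0, 3),
    mG_star = stats::runif(1), tGEF = stats::runif(1, 0, 3),
    tG_star = stats::runif(1), mGAP = stats::runif(1, 0, 3)
  )
}
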
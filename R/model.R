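#' Reaction kinetics f
#'
#' Rate law applied to every regulator in the cascade. Under mass-action
#' kinetics `f(x) = x`; under Hill kinetics
#' `f(x) = x^n / (K^n + x^n)`, the activation Hill function, which is
#' monotone nondecreasing with values in \[0, 1).
#'
#' @param x nonnegative scalar or vector argument.
#' @param spec a [model_spec()] selecting the kinetics (and Hill constants).
#' @return `f(x)`, same length as `x`.
#' @examples
#' kinetic_f(0.37, model_spec("mass_action"))            # 0.37
#' kinetic_f(0.5, model_spec("hill", hill = hill_spec(K = 0.5, n = 2)))  # 0.5
#' @export
kinetic_f <- function(x, spec) {
  if (any(!is.finite(x))) stop("argument of f must be finite")
  if (any(x < 0)) stop("argument of f must be nonnegative")
  if (spec$kinetics == "mass_action") {
    x
  } else {
    K <- spec$hill$K
    n <- spec$hill$n
    xn <- (x / K)^n          # scale first: robust for large x and n
    ifelse(is.infinite(xn), 1, xn / (1 + xn))
  }
}

#' Feedback crosstalk term F(tGEF, tG*)
#'
#' Joint drive of tGEF and active tGTPase on mGAP production. With no
#' feedback the term is identically zero; the AND gate multiplies the two
#' single-regulator rates, the OR gate adds them. Both use the same
#' kinetics `f` as the rest of the model.
#'
#' @param tGEF nonnegative tGEF concentration.
#' @param tG_star fractional tGTPase activation.
#' @param spec a [model_spec()].
#' @return Nonnegative scalar feedback drive (before multiplication by
#'   `k_feedback`).
#' @export
feedback_F <- function(tGEF, tG_star, spec) {
  if (any(tGEF < 0) || any(tG_star < 0)) stop("feedback inputs must be nonnegative")
  switch(spec$feedback_logic,
    none = 0 * tGEF,
    and  = kinetic_f(tGEF, spec) * kinetic_f(tG_star, spec),
    or   = kinetic_f(tGEF, spec) + kinetic_f(tG_star, spec)
  )
}

#' Right-hand side of the six-variable cascade ODE system
#'
#' Time derivatives of (R*, mGEF, mG*, tGEF, tG*, mGAP) at stimulus dose
#' `S`. Activation of each fractional species is driven by `f` of its GEF
#' (or the stimulus, for the receptor) acting on the inactive pool, and
#' deactivation by `f` of its GAP; mGAP is produced constitutively at
#' `k_on_mGAP` plus the feedback term `k_feedback * F(tGEF, tG*)`.
#'
#' @param state named numeric vector with entries `R_star`, `mGEF`,
#'   `mG_star`, `tGEF`, `tG_star`, `mGAP`.
#' @param S stimulus dose, nonnegative.
#' @param params a [kinetic_parameters()] object.
#' @param spec a [model_spec()].
#' @return Named numeric vector of the six time derivatives.
#' @export
cascade_rhs <- function(state, S, params, spec) {
  if (!all(is.finite(state))) stop("state must be finite")
  if (!is.finite(S) || S < 0) stop("stimulus S must be a nonnegative number")
  p <- params
  f <- function(x) kinetic_f(x, spec)
  R <- state[["R_star"]]; mGEF <- state[["mGEF"]]; mG <- state[["mG_star"]]
  tGEF <- state[["tGEF"]]; tG <- state[["tG_star"]]; mGAP <- state[["mGAP"]]
  c(
    R_star  = p$k_on_R * f(S) * (1 - R) - p$k_off_R * R,
    mGEF    = p$k_on_mGEF * f(R) - p$k_off_mGEF * mGEF,
    mG_star = p$k_on_mG * f(mGEF) * (1 - mG) - p$k_off_mG * f(mGAP) * mG,
    tGEF    = p$k_on_tGEF * f(mG) - p$k_off_tGEF * tGEF,
    tG_star = p$k_on_tG * f(tGEF) * (1 - tG) - p$k_off_tG * f(p$tGAP) * tG,
    mGAP    = p$k_on_mGAP + p$k_feedback * feedback_F(tGEF, tG, spec) -
              p$k_off_mGAP * mGAP
  )
}
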
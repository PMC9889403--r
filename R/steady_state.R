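#' Derived composite constants of the closed-form steady states
#'
#' Lumped parameter combinations that appear in the analytic steady-state
#' expressions: `a_M`, `b_M` for the mass-action cascade without feedback,
#' `c`, `d`, `e` for the mass-action feedback fixed point, and `a_H`, `b_H`
#' for the Hill cascade without feedback. The mGAP steady state entering
#' `a_M` and `a_H` is the constitutive (no-feedback) level
#' `k_on_mGAP / k_off_mGAP`.
#'
#' @param params a [kinetic_parameters()] object.
#' @param spec a [model_spec()]; Hill constants are taken from it.
#' @return Named list with `a_M`, `b_M`, `c`, `d`, `e`, `a_H`, `b_H` and
#'   `mGAP_ss0` (the no-feedback mGAP steady state).
#' @export
derived_constants <- function(params, spec = model_spec()) {
  p <- params
  mGAP0 <- p$k_on_mGAP / p$k_off_mGAP
  hillf <- function(x) kinetic_f(x, model_spec("hill", hill = spec$hill))
  list(
    mGAP_ss0 = mGAP0,
    a_M = mGAP0 * (p$k_off_mGEF * p$k_off_mG) / (p$k_on_mG * p$k_on_mGEF),
    b_M = p$tGAP * (p$k_off_tGEF * p$k_off_tG) / (p$k_on_tG * p$k_on_tGEF),
    c = (p$k_on_mGAP * p$k_off_mGEF * p$k_off_mG) /
        (p$k_off_mGAP * p$k_on_mG * p$k_on_mGEF),
    d = (p$k_on_tGEF * p$k_off_mGEF * p$k_off_mG) /
        (p$k_off_mGAP * p$k_off_tGEF * p$k_on_mG * p$k_on_mGEF),
    e = (p$k_off_mGEF * p$k_off_mG) /
        (p$k_off_mGAP * p$k_on_mG * p$k_on_mGEF),
    # reciprocal rate ratios: required for mG* = F1/(F1 + a_H) to solve
    # k_on_mG f(mGEF)(1 - mG*) = k_off_mG f(mGAP) mG*, and likewise for tG*
    a_H = (p$k_off_mG / p$k_on_mG) * hillf(mGAP0),
    b_H = (p$k_off_tG / p$k_on_tG) * hillf(p$tGAP)
  )
}

#' Steady-state receptor occupancy
#'
#' The receptor equation decouples from the rest of the cascade, so its
#' steady state is available in closed form:
#' `k_on_R * f(S) / (k_on_R * f(S) + k_off_R)` with `f` the identity
#' (mass action) or the activation Hill function.
#'
#' @param S stimulus dose (scalar or vector), nonnegative.
#' @inheritParams derived_constants
#' @return Fractional receptor activation in \[0, 1).
#' @export
receptor_steady <- function(S, params, spec) {
  drive <- params$k_on_R * kinetic_f(S, spec)
  drive / (drive + params$k_off_R)
}

#' Maximal receptor activation (infinite-stimulus limit)
#'
#' Equals 1 under mass action (the drive grows without bound) and
#' `k_on_R / (k_on_R + k_off_R)` under Hill kinetics, where `f(S)`
#' saturates at 1.
#'
#' @inheritParams derived_constants
#' @return Scalar limit of [receptor_steady()] as `S` grows.
#' @export
receptor_max <- function(params, spec) {
  if (spec$kinetics == "mass_action") {
    1
  } else {
    params$k_on_R / (params$k_on_R + params$k_off_R)
  }
}

# Reconstruct the full steady state from mG* = y at receptor occupancy
# R_star. Every other component follows y through one closed-form layer.
reconstruct_steady <- function(y, R_star, params, spec) {
  p <- params
  f <- function(x) kinetic_f(x, spec)
  mGEF <- (p$k_on_mGEF / p$k_off_mGEF) * f(R_star)
  tGEF <- (p$k_on_tGEF / p$k_off_tGEF) * f(y)
  act_t <- p$k_on_tG * f(tGEF)
  den_t <- act_t + p$k_off_tG * f(p$tGAP)
  tG <- if (den_t > 0) act_t / den_t else 0
  mGAP <- (p$k_on_mGAP + p$k_feedback * feedback_F(tGEF, tG, spec)) / p$k_off_mGAP
  c(R_star = R_star, mGEF = mGEF, mG_star = y,
    tGEF = tGEF, tG_star = tG, mGAP = mGAP)
}

# Self-consistent mG* map: g(y) is the mG* implied by the state built from
# y. g is nonincreasing in y (feedback raises mGAP), so y - g(y) has a
# unique root on [0, 1].
fixed_point_map <- function(y, R_star, params, spec) {
  p <- params
  st <- reconstruct_steady(y, R_star, params, spec)
  act <- p$k_on_mG * kinetic_f(st[["mGEF"]], spec)
  den <- act + p$k_off_mG * kinetic_f(st[["mGAP"]], spec)
  if (den > 0) act / den else 0
}

#' Steady state by scalar fixed-point root-finding
#'
#' Reduces the full steady-state problem to one scalar equation in
#' `y = mG*_ss`: every other component is an explicit function of `y` (and
#' the closed-form receptor occupancy), and `y` must equal the mGTPase
#' activation implied by the mGEF and mGAP levels it generates. The
#' residual `y - g(y)` is monotone increasing, so a bracketed root on
#' \[0, 1\] is unique; it is found with [stats::uniroot()].
#'
#' @param S stimulus dose, nonnegative scalar.
#' @inheritParams derived_constants
#' @param tol root-finder tolerance on `y`.
#' @return A [system_state()] vector of the six steady components.
#' @seealso [steady_state_ode()] for the integration route.
#' @export
steady_state_fixed_point <- function(S, params, spec, tol = 1e-12) {
  if (!is.finite(S) || S < 0) stop("stimulus S must be a nonnegative number")
  R_star <- receptor_steady(S, params, spec)
  steady_state_at_receptor(R_star, params, spec, tol = tol)
}

# Fixed point at a prescribed receptor occupancy (used both per dose and at
# the infinite-stimulus limit R_star = receptor_max).
steady_state_at_receptor <- function(R_star, params, spec, tol = 1e-12) {
  resid <- function(y) y - fixed_point_map(y, R_star, params, spec)
  r0 <- resid(0)
  r1 <- resid(1)
  y <- if (r0 == 0) {
    0
  } else if (r0 > 0 || r1 < 0) {
    # cannot happen for this vector field; surface it rather than guessing
    stop("no sign change of the fixed-point residual on [0, 1]; ",
         "possible multistability (resid(0) = ", signif(r0, 6),
         ", resid(1) = ", signif(r1, 6), ")")
  } else {
    stats::uniroot(resid, lower = 0, upper = 1, f.lower = r0, f.upper = r1,
                   tol = tol)$root
  }
  st <- reconstruct_steady(y, R_star, params, spec)
  structure(st, class = "system_state")
}

#' Steady state by stiff ODE integration
#'
#' Integrates the six-variable system from a default all-zero (inactive)
#' initial condition to long time with a stiff solver
#' ([deSolve::ode()], `lsoda`). Integration proceeds in geometric time
#' chunks and stops early once the residual norm of the right-hand side
#' satisfies `max |dx/dt| < tol * (1 + |x|)` componentwise; reaching
#' `t_end` without convergence is an error carrying the residual.
#'
#' @param S stimulus dose, nonnegative scalar.
#' @inheritParams derived_constants
#' @param t_end final integration time (default `1e8`).
#' @param tol convergence tolerance on the scaled residual.
#' @param init optional initial [system_state()]; defaults to all zeros.
#' @param atol,rtol absolute / relative integrator tolerances.
#' @return A [system_state()] vector of the six steady components.
#' @export
steady_state_ode <- function(S, params, spec, t_end = 1e8, tol = 1e-9,
                             init = NULL, atol = 1e-12, rtol = 1e-10) {
  if (!is.finite(S) || S < 0) stop("stimulus S must be a nonnegative number")
  state <- if (is.null(init)) {
    c(R_star = 0, mGEF = 0, mG_star = 0, tGEF = 0, tG_star = 0, mGAP = 0)
  } else {
    validate_system_state(init)
    unclass(init)[.state_fields]
  }
  deriv <- function(t, y, parms) list(cascade_rhs(y, S, params, spec))
  converged_at <- function(y) {
    d <- cascade_rhs(y, S, params, spec)
    all(abs(d) < tol * (1 + abs(y)))
  }
  t0 <- 0
  t1 <- 1
  repeat {
    out <- deSolve::ode(y = state, times = c(t0, t1), func = deriv,
                        parms = NULL, method = "lsoda",
                        atol = atol, rtol = rtol)
    if (attr(out, "istate")[1L] < 0) {
      stop("stiff integrator failed at S = ", S, " before t = ", t1)
    }
    state <- out[nrow(out), .state_fields]
    if (converged_at(state)) break
    if (t1 >= t_end) {
      d <- cascade_rhs(state, S, params, spec)
      stop("steady state not reached by t = ", t_end, " at S = ", S,
           "; max scaled residual = ",
           signif(max(abs(d) / (1 + abs(state))), 6))
    }
    t0 <- t1
    t1 <- min(t1 * 100, t_end)
  }
  # clamp integrator noise at the invariant-box boundary
  state[.fractional_fields] <- pmin(pmax(state[.fractional_fields], 0), 1)
  structure(state, class = "system_state")
}

#' Closed-form mass-action steady state without feedback
#'
#' For mass-action kinetics and no feedback the GTPase steady states are
#' Michaelian in the receptor occupancy:
#' `mG* = R* / (R* + a_M)` and `tG* = mG* / (mG* + b_M)`.
#'
#' @param R_star receptor occupancy (scalar or vector in \[0, 1\]).
#' @param params a [kinetic_parameters()]; must have `k_feedback = 0`
#'   unless composite constants are supplied directly.
#' @param a_M,b_M optional composite constants overriding `params`.
#' @return List with vectors `mG_star` and `tG_star`.
#' @export
analytic_mass_action_steady <- function(R_star, params = NULL,
                                        a_M = NULL, b_M = NULL) {
  if (any(R_star < 0) || any(R_star > 1)) stop("R_star must lie in [0, 1]")
  if (is.null(a_M) || is.null(b_M)) {
    if (is.null(params)) stop("supply either params or both a_M and b_M")
    if (params$k_feedback != 0) {
      stop("closed form is valid only without feedback (k_feedback = 0)")
    }
    dc <- derived_constants(params)
    a_M <- a_M %||% dc$a_M
    b_M <- b_M %||% dc$b_M
  }
  mG <- ifelse(R_star + a_M > 0, R_star / (R_star + a_M),
               as.numeric(R_star > 0))
  tG <- ifelse(mG + b_M > 0, mG / (mG + b_M), as.numeric(mG > 0))
  list(mG_star = mG, tG_star = tG)
}

#' Closed-form Hill steady state without feedback
#'
#' With Hill kinetics and no feedback the cascade steady states are nested
#' Hill compositions of the receptor occupancy:
#' `mG* = F1(R*) / (F1(R*) + a_H)` with
#' `F1(R*) = f_act((k_on_mGEF/k_off_mGEF) f_act(R*))`, and
#' `tG* = F2(R*) / (F2(R*) + b_H)` with
#' `F2(R*) = f_act((k_on_tGEF/k_off_tGEF) f_act(mG*))`.
#'
#' @param R_star receptor occupancy (scalar or vector in \[0, 1\]).
#' @param params a [kinetic_parameters()] with `k_feedback = 0`.
#' @param hill a [hill_spec()].
#' @return List with vectors `mG_star`, `tG_star`, `F1`, `F2`.
#' @export
analytic_hill_steady <- function(R_star, params, hill = hill_spec()) {
  if (params$k_feedback != 0) {
    stop("closed form is valid only without feedback (k_feedback = 0)")
  }
  if (any(R_star < 0) || any(R_star > 1)) stop("R_star must lie in [0, 1]")
  sp <- model_spec("hill", hill = hill)
  f <- function(x) kinetic_f(x, sp)
  dc <- derived_constants(params, sp)
  F1 <- f((params$k_on_mGEF / params$k_off_mGEF) * f(R_star))
  mG <- F1 / (F1 + dc$a_H)
  F2 <- f((params$k_on_tGEF / params$k_off_tGEF) * f(mG))
  tG <- F2 / (F2 + dc$b_H)
  list(mG_star = mG, tG_star = tG, F1 = F1, F2 = F2)
}

#' Activation levels (infinite-stimulus steady states)
#'
#' Computes the `S -> Inf` limits used to normalize dose-response curves:
#' the receptor limit in closed form and the GTPase limits by solving the
#' steady-state fixed point at `R* = R*_max`. `mG_max` is the mGTPase
#' activation level that organizes all regime classifications.
#'
#' @inheritParams derived_constants
#' @return Named numeric vector `c(R_max, mG_max, tG_max)`.
#' @export
activation_levels <- function(params, spec) {
  R_max <- receptor_max(params, spec)
  st <- steady_state_at_receptor(R_max, params, spec)
  c(R_max = R_max, mG_max = st[["mG_star"]], tG_max = st[["tG_star"]])
}

#' Default logarithmic dose grid
#'
#' @param n number of grid points (default 60).
#' @param lo,hi dose range endpoints (defaults `1e-5` and `1e3`).
#' @return Strictly increasing positive dose vector.
#' @export
default_dose_grid <- function(n = 60, lo = 1e-5, hi = 1e3) {
  10^seq(log10(lo), log10(hi), length.out = n)
}

#' Steady-state dose-response curve
#'
#' Computes the six steady-state components on a dose grid (via the scalar
#' fixed point by default, or by stiff ODE integration as a cross-check
#' mode) together with the infinite-stimulus activation levels.
#'
#' @inheritParams derived_constants
#' @param S_grid strictly increasing positive dose vector.
#' @param method `"fixed_point"` (default) or `"ode"`.
#' @return An object of class `dose_response_curve`: a list with `curve`
#'   (data frame of `S` plus the six components), `R_max`, `mG_max`,
#'   `tG_max`, `params`, `spec`.
#' @export
dose_response <- function(params, spec, S_grid = default_dose_grid(),
                          method = c("fixed_point", "ode")) {
  method <- match.arg(method)
  if (any(S_grid <= 0) || any(diff(S_grid) <= 0)) {
    stop("S_grid must be strictly increasing and positive")
  }
  solver <- switch(method,
    fixed_point = function(S) steady_state_fixed_point(S, params, spec),
    ode = function(S) steady_state_ode(S, params, spec)
  )
  states <- t(vapply(S_grid, function(S) {
    tryCatch(unclass(solver(S)),
             error = function(e) stop("steady-state solve failed at S = ", S,
                                      ": ", conditionMessage(e)))
  }, numeric(6)))
  lev <- activation_levels(params, spec)
  structure(list(
    curve = data.frame(S = S_grid, states),
    R_max = lev[["R_max"]], mG_max = lev[["mG_max"]], tG_max = lev[["tG_max"]],
    params = params, spec = spec
  ), class = "dose_response_curve")
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat("Dose-response curve:", nrow(x$curve), "doses on [",
      format(min(x$curve$S)), ",", format(max(x$curve$S)), "]\n")
  cat("  kinetics:", x$spec$kinetics,
      " feedback:", x$spec$feedback_logic, "\n")
  cat("  activation levels: R_max =", signif(x$R_max, 6),
      " mG_max =", signif(x$mG_max, 6),
      " tG_max =", signif(x$tG_max, 6), "\n")
  invisible(x)
}

#' Write a dose-response curve as annotated tidy CSV
#'
#' Writes one row per dose with columns `S, R_star, mGEF, mG_star, tGEF,
#' tG_star, mGAP`, preceded by a `#`-commented header block recording the
#' parameter set, model spec, activation levels and grid.
#'
#' @param x a `dose_response_curve`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_dose_response <- function(x, file) {
  cfg <- model_to_config(x$params, x$spec)
  hdr <- c(
    "# doraswitch dose-response curve",
    paste0("# ", names(cfg), " = ", unlist(cfg)),
    paste0("# R_max = ", format(x$R_max, digits = 17)),
    paste0("# mG_max = ", format(x$mG_max, digits = 17)),
    paste0("# tG_max = ", format(x$tG_max, digits = 17)),
    paste0("# n_doses = ", nrow(x$curve))
  )
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(format(x$curve, digits = 17, trim = TRUE,
                          scientific = NA),
                   con, row.names = FALSE, quote = FALSE)
  invisible(file)
}
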
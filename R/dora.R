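#' Normalized dose-response curves
#'
#' Divides each species' dose-response curve by its own infinite-stimulus
#' activation level, producing the curves the alignment metric compares:
#' `u = R*/R*_max` and `v = Y/Y_max` for `Y` in {mG*, tG*}.
#'
#' @param curve a `dose_response_curve` from [dose_response()].
#' @return An object of class `normalized_curves`: list with `S`, `u`,
#'   `v_mG`, `v_tG` and the originating `params`/`spec` (used for the
#'   analytic receptor derivative in the dose-weighted metric form).
#' @export
normalize_curves <- function(curve) {
  if (!inherits(curve, "dose_response_curve")) {
    stop("`curve` must be a dose_response_curve")
  }
  if (curve$R_max <= 0 || curve$mG_max <= 0 || curve$tG_max <= 0) {
    stop("degenerate model: an activation level is zero, cannot normalize")
  }
  structure(list(
    S = curve$curve$S,
    u = curve$curve$R_star / curve$R_max,
    v_mG = curve$curve$mG_star / curve$mG_max,
    v_tG = curve$curve$tG_star / curve$tG_max,
    params = curve$params, spec = curve$spec
  ), class = "normalized_curves")
}

#' Construct normalized curves directly
#'
#' Builds a `normalized_curves` object from explicit `u`/`v` samples
#' (e.g. analytically defined test curves).
#'
#' @param u normalized receptor occupancy samples, nondecreasing in \[0, 1\].
#' @param v_mG,v_tG normalized downstream curves on the same grid.
#' @param S optional dose grid.
#' @return A `normalized_curves` object.
#' @export
normalized_curves <- function(u, v_mG, v_tG = v_mG, S = NULL) {
  if (any(u < 0 | u > 1 + 1e-12)) stop("u must lie in [0, 1]")
  structure(list(S = S, u = u, v_mG = v_mG, v_tG = v_tG,
                 params = NULL, spec = NULL),
            class = "normalized_curves")
}

#' DoRA distance metric
#'
#' The alignment distance between a normalized downstream curve `v` and
#' the normalized receptor curve `u`: the dose integral of `|v - u|`
#' weighted by `du/dS`, which by substitution equals the area between the
#' curve `v(u)` and the diagonal in the `v`-vs-`u` plane. Zero means
#' perfect alignment. Evaluated by the trapezoidal rule on the `u`-ordered
#' samples; because both normalized curves approach 1 at infinite
#' stimulus, the exact endpoint `(u, v) = (1, 1)` is appended when the
#' finite grid stops short of it.
#'
#' @param norm a `normalized_curves` object.
#' @param species `"mG"` or `"tG"`: which downstream curve to compare.
#' @param extend append the analytic `(1, 1)` endpoint (default `TRUE`).
#' @return Nonnegative scalar distance.
#' @examples
#' u <- seq(0, 1, length.out = 101)
#' dora_metric(normalized_curves(u, u))        # perfect alignment: 0
#' dora_metric(normalized_curves(u, rep(1, 101)))  # saturated curve: 0.5
#' @export
dora_metric <- function(norm, species = c("mG", "tG"), extend = TRUE) {
  species <- match.arg(species)
  u <- norm$u
  v <- if (species == "mG") norm$v_mG else norm$v_tG
  if (length(u) < 2L) stop("need at least 2 grid points")
  o <- order(u)
  u <- u[o]; v <- v[o]
  if (extend && u[length(u)] < 1) {
    u <- c(u, 1)
    v <- c(v, 1)
  }
  trapz(u, abs(v - u))
}

trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Analytic derivative of normalized receptor occupancy with respect to dose
#'
#' `du/dS` for `u = R*_ss(S) / R*_max`, available in closed form for both
#' kinetics; this is the weight of the dose-integral form of the distance
#' metric.
#'
#' @param S dose (scalar or vector).
#' @inheritParams derived_constants
#' @return `du/dS` evaluated at `S`.
#' @export
receptor_steady_deriv <- function(S, params, spec) {
  a <- params$k_on_R
  b <- params$k_off_R
  if (spec$kinetics == "mass_action") {
    a * b / (a * S + b)^2    # R_max = 1
  } else {
    f <- kinetic_f(S, spec)
    n <- spec$hill$n
    fp <- ifelse(S > 0, n * f * (1 - f) / S, ifelse(n < 1, Inf, n == 1))
    R_max <- a / (a + b)
    (a * b * fp / (a * f + b)^2) / R_max
  }
}

#' Dose-integral and area forms of the distance metric
#'
#' Cross-checks the two printed definitions of the metric on one model:
#' the dose-weighted integral `int |v - u| (du/dS) dS` evaluated by the
#' trapezoidal rule in `S` with the analytic receptor derivative, and the
#' substituted area form `int |v - u| du` evaluated by the trapezoidal
#' rule in `u`. Both are restricted to the common dose window (no endpoint
#' extension) so that they estimate the same integral and differ only by
#' quadrature error, which vanishes under grid refinement.
#'
#' @inheritParams derived_constants
#' @param S_grid dose grid; dense by default since this is a
#'   numerical-equivalence check.
#' @param species `"mG"` or `"tG"`.
#' @return List with `integral_form`, `area_form`, `discrepancy`.
#' @export
metric_area_equivalence <- function(params, spec,
                                    S_grid = default_dose_grid(4001),
                                    species = c("mG", "tG")) {
  species <- match.arg(species)
  drc <- dose_response(params, spec, S_grid)
  norm <- normalize_curves(drc)
  v <- if (species == "mG") norm$v_mG else norm$v_tG
  w <- abs(v - norm$u)
  dudS <- receptor_steady_deriv(norm$S, params, spec)
  integral_form <- trapz(norm$S, w * dudS)
  area_form <- trapz(norm$u, w)
  list(integral_form = integral_form, area_form = area_form,
       discrepancy = abs(integral_form - area_form))
}

# h(y, k_feedback) of the mass-action feedback fixed point
# y = x / (x + c + h(y)), plus its partial derivative in y.
feedback_h <- function(y, params, spec, dc = derived_constants(params, spec)) {
  k <- params$k_feedback
  if (spec$feedback_logic == "and") {
    h <- k * dc$d * y^2 / (y + dc$b_M)
    dh <- k * dc$d * y * (y + 2 * dc$b_M) / (y + dc$b_M)^2
  } else if (spec$feedback_logic == "or") {
    h <- k * (dc$d * y + dc$e * y / (y + dc$b_M))
    dh <- k * (dc$d + dc$e * dc$b_M / (y + dc$b_M)^2)
  } else {
    stop("feedback_h requires an AND or OR feedback model")
  }
  list(h = h, dh_dy = dh)
}

# (1/y) dy/dk_feedback from the closed-form decomposition of the
# mass-action feedback fixed point.
dlog_y_dk <- function(y, params, spec, dc) {
  k <- params$k_feedback
  fh <- feedback_h(y, params, spec, dc)
  denom <- (y / fh$h) * fh$dh_dy +
    ((dc$c + fh$h) / fh$h) / (1 - y)
  -(1 / k) / denom
}

#' Closed-form feedback sensitivity of the normalized mGTPase curve
#'
#' Evaluates `d(y / y_max) / d k_feedback` for the mass-action feedback
#' model, where `y = mG*_ss(S)` and `y_max = mG*_ss,max`, using the
#' closed-form logarithmic derivative
#' `(1/y) dy/dk = -(1/k) / [ (y/h) dh/dy + ((c + h)/h) / (1 - y) ]`
#' of the scalar fixed point, evaluated at `y` and at `y_max`.
#'
#' @inheritParams derived_constants
#' @param S stimulus dose (scalar or vector).
#' @return `d(y/y_max)/dk_feedback` at each `S`.
#' @export
feedback_derivative_mass_action <- function(params, spec, S) {
  if (spec$kinetics != "mass_action") {
    stop("closed-form feedback derivative is mass-action only")
  }
  if (spec$feedback_logic == "none") {
    stop("feedback derivative requires an AND or OR feedback model")
  }
  if (params$k_feedback <= 0) {
    stop("closed form divides by k_feedback; use a finite difference at 0")
  }
  dc <- derived_constants(params, spec)
  y_max <- steady_state_at_receptor(receptor_max(params, spec),
                                    params, spec)[["mG_star"]]
  gmax <- dlog_y_dk(y_max, params, spec, dc)
  vapply(S, function(s) {
    y <- steady_state_fixed_point(s, params, spec)[["mG_star"]]
    if (y <= 0) return(0)
    (dlog_y_dk(y, params, spec, dc) - gmax) * y / y_max
  }, numeric(1))
}

#' Derivative of the distance metric with respect to feedback strength
#'
#' For the mass-action model the normalized mGTPase curve never drops
#' below the receptor curve, so `d(metric)/dk_feedback` is obtained by
#' differentiating under the integral with the closed-form sensitivity
#' [feedback_derivative_mass_action()]. For Hill kinetics (where no closed
#' form is available) a central finite difference of the full metric is
#' used. Both modes are exposed for cross-checking.
#'
#' @inheritParams derived_constants
#' @param species `"mG"` or `"tG"` (analytic mode: `"mG"` only).
#' @param method `"analytic"` or `"finite_difference"`.
#' @param S_grid dose grid for the metric quadrature.
#' @param rel_step relative step of the central difference.
#' @return Scalar derivative of the metric with respect to `k_feedback`.
#' @export
metric_derivative_wrt_feedback <- function(params, spec, species = "mG",
                                           method = c("analytic",
                                                      "finite_difference"),
                                           S_grid = default_dose_grid(),
                                           rel_step = 1e-4) {
  method <- match.arg(method)
  if (method == "analytic") {
    if (spec$kinetics != "mass_action" || species != "mG") {
      stop("analytic metric derivative available for the mass-action ",
           "mGTPase metric only; use method = \"finite_difference\"")
    }
    drc <- dose_response(params, spec, S_grid)
    norm <- normalize_curves(drc)
    dv <- feedback_derivative_mass_action(params, spec, norm$S)
    # v >= u pointwise under mass action, so d|v-u|/dk = dv/dk; the
    # appended endpoint (u = 1) has v fixed at 1, hence sensitivity 0
    trapz(c(norm$u, 1), c(dv, 0))
  } else {
    k0 <- params$k_feedback
    h <- if (k0 > 0) rel_step * k0 else rel_step
    m <- function(k) {
      p <- params
      p$k_feedback <- k
      norm <- normalize_curves(dose_response(p, spec, S_grid))
      dora_metric(norm, species)
    }
    lower <- max(k0 - h, 0)
    (m(k0 + h) - m(lower)) / (k0 + h - lower)
  }
}
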
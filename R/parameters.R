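#' Kinetic parameter set for the coupled GTPase switch model
#'
#' Bundles every rate constant of the six-variable cascade together with the
#' negative-feedback strength and the (constant) tGAP concentration. All
#' `k_on`/`k_off` values are first-order rate constants (per unit time);
#' `tGAP` is a fixed concentration, not a dynamic variable.
#'
#' @param k_on_R,k_off_R receptor activation / deactivation rate constants.
#' @param k_on_mGEF,k_off_mGEF mGEF production / decay rate constants.
#' @param k_on_mG,k_off_mG mGTPase activation / deactivation rate constants.
#' @param k_on_tGEF,k_off_tGEF tGEF production / decay rate constants.
#' @param k_on_tG,k_off_tG tGTPase activation / deactivation rate constants.
#' @param k_on_mGAP,k_off_mGAP constitutive mGAP production / decay rate
#'   constants.
#' @param k_feedback nonnegative strength of the negative feedback from
#'   tGEF and active tGTPase onto mGAP production.
#' @param tGAP constant tGAP concentration.
#'
#' @return An object of class `kinetic_parameters` (a named list).
#' @examples
#' p <- kinetic_parameters()          # unit rates, no feedback
#' p$k_feedback
#' @export
kinetic_parameters <- function(k_on_R = 1, k_off_R = 1,
                               k_on_mGEF = 1, k_off_mGEF = 1,
                               k_on_mG = 1, k_off_mG = 1,
                               k_on_tGEF = 1, k_off_tGEF = 1,
                               k_on_tG = 1, k_off_tG = 1,
                               k_on_mGAP = 1, k_off_mGAP = 1,
                               k_feedback = 0, tGAP = 1) {
  p <- list(
    k_on_R = k_on_R, k_off_R = k_off_R,
    k_on_mGEF = k_on_mGEF, k_off_mGEF = k_off_mGEF,
    k_on_mG = k_on_mG, k_off_mG = k_off_mG,
    k_on_tGEF = k_on_tGEF, k_off_tGEF = k_off_tGEF,
    k_on_tG = k_on_tG, k_off_tG = k_off_tG,
    k_on_mGAP = k_on_mGAP, k_off_mGAP = k_off_mGAP,
    k_feedback = k_feedback, tGAP = tGAP
  )
  validate_kinetic_parameters(p)
  structure(p, class = "kinetic_parameters")
}

#' @rdname kinetic_parameters
#' @param x object to test or validate.
#' @export
is_kinetic_parameters <- function(x) inherits(x, "kinetic_parameters")

# Fields whose reciprocal enters a closed-form expression; they must be
# strictly positive so the analytic steady states are well defined.
.divisor_fields <- c("k_off_R", "k_off_mGEF", "k_off_mG", "k_off_tGEF",
                     "k_off_tG", "k_off_mGAP")

.param_fields <- c("k_on_R", "k_off_R", "k_on_mGEF", "k_off_mGEF",
                   "k_on_mG", "k_off_mG", "k_on_tGEF", "k_off_tGEF",
                   "k_on_tG", "k_off_tG", "k_on_mGAP", "k_off_mGAP",
                   "k_feedback", "tGAP")

validate_kinetic_parameters <- function(p) {
  missing <- setdiff(.param_fields, names(p))
  if (length(missing) > 0L) {
    stop("missing kinetic parameter field(s): ", paste(missing, collapse = ", "))
  }
  vals <- unlist(p[.param_fields])
  if (!all(is.finite(vals))) {
    stop("kinetic parameters must be finite numbers")
  }
  if (any(vals < 0)) {
    bad <- .param_fields[vals < 0]
    stop("kinetic parameter(s) must be nonnegative: ", paste(bad, collapse = ", "))
  }
  div <- unlist(p[.divisor_fields])
  if (any(div <= 0)) {
    bad <- .divisor_fields[div <= 0]
    stop("decay rate constant(s) must be strictly positive: ",
         paste(bad, collapse = ", "))
  }
  invisible(p)
}

#' Hill activation specification
#'
#' Parameters of the activation Hill function
#' \eqn{f_{act}(x) = x^n / (K^n + x^n)}: `K` is the half-maximal activation
#' (same units as the argument) and `n` the dimensionless Hill coefficient.
#'
#' @param K half-maximal activation, strictly positive.
#' @param n Hill coefficient, strictly positive.
#' @return An object of class `hill_spec`.
#' @export
hill_spec <- function(K = 0.5, n = 1.5) {
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0) {
    stop("Hill constant K must be a single positive number")
  }
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0) {
    stop("Hill coefficient n must be a single positive number")
  }
  structure(list(K = K, n = n), class = "hill_spec")
}

#' Model specification: kinetics and feedback logic
#'
#' Selects one of the six model variants: mass-action or Hill kinetics for
#' the reaction rates, combined with no feedback, an AND logic gate
#' (`f(tGEF) * f(tG*)`), or an OR logic gate (`f(tGEF) + f(tG*)`) for the
#' negative-feedback crosstalk onto mGAP.
#'
#' @param kinetics `"mass_action"` or `"hill"`.
#' @param feedback_logic `"none"`, `"and"`, or `"or"`.
#' @param hill a [hill_spec()]; ignored for mass-action kinetics.
#' @return An object of class `model_spec`.
#' @examples
#' model_spec("hill", "and", hill_spec(K = 0.5, n = 1.5))
#' @export
model_spec <- function(kinetics = c("mass_action", "hill"),
                       feedback_logic = c("none", "and", "or"),
                       hill = hill_spec()) {
  kinetics <- match.arg(kinetics)
  feedback_logic <- match.arg(feedback_logic)
  if (!inherits(hill, "hill_spec")) stop("`hill` must be a hill_spec object")
  structure(list(kinetics = kinetics, feedback_logic = feedback_logic,
                 hill = hill),
            class = "model_spec")
}

#' @rdname model_spec
#' @param x object to test.
#' @export
is_model_spec <- function(x) inherits(x, "model_spec")

#' System state of the cascade
#'
#' The six dynamic variables at one stimulus dose: fractional activations
#' `R_star`, `mG_star`, `tG_star` (dimensionless, in \[0, 1\]) and
#' concentrations `mGEF`, `tGEF`, `mGAP` (nonnegative).
#'
#' @param R_star,mG_star,tG_star fractional activations in \[0, 1\].
#' @param mGEF,tGEF,mGAP nonnegative concentrations.
#' @return A named numeric vector of class `system_state`.
#' @export
system_state <- function(R_star = 0, mGEF = 0, mG_star = 0,
                         tGEF = 0, tG_star = 0, mGAP = 0) {
  s <- c(R_star = R_star, mGEF = mGEF, mG_star = mG_star,
         tGEF = tGEF, tG_star = tG_star, mGAP = mGAP)
  validate_system_state(s)
  structure(s, class = "system_state")
}

.state_fields <- c("R_star", "mGEF", "mG_star", "tGEF", "tG_star", "mGAP")
.fractional_fields <- c("R_star", "mG_star", "tG_star")

validate_system_state <- function(s, tol = 1e-9) {
  if (!all(.state_fields %in% names(s))) {
    stop("state must contain fields: ", paste(.state_fields, collapse = ", "))
  }
  if (!all(is.finite(s[.state_fields]))) stop("state must be finite")
  fr <- s[.fractional_fields]
  if (any(fr < -tol) || any(fr > 1 + tol)) {
    stop("fractional activations must lie in [0, 1]")
  }
  if (any(s[c("mGEF", "tGEF", "mGAP")] < -tol)) {
    stop("concentrations must be nonnegative")
  }
  invisible(s)
}

#' Serialize parameters and model spec to a flat key-value configuration
#'
#' Writes (or builds) a flat named list in which kinetic parameters keep
#' their model symbols (`k_on_mGAP`, ...) and the model choice appears as
#' `kinetics`, `feedback_logic`, `hill_K`, `hill_n`. The list round-trips
#' through YAML or JSON.
#'
#' @param params a [kinetic_parameters()] object.
#' @param spec a [model_spec()] object.
#' @param file optional path; when given, the config is written as YAML
#'   (`.yml`/`.yaml`) or JSON (anything else).
#' @return The flat named list, invisibly when `file` is given.
#' @seealso [config_to_model()] for the inverse.
#' @export
model_to_config <- function(params, spec, file = NULL) {
  validate_kinetic_parameters(params)
  cfg <- c(unclass(params)[.param_fields],
           list(kinetics = spec$kinetics,
                feedback_logic = spec$feedback_logic,
                hill_K = spec$hill$K,
                hill_n = spec$hill$n))
  if (is.null(file)) return(cfg)
  if (grepl("\\.ya?ml$", file)) {
    yaml::write_yaml(cfg, file)
  } else {
    jsonlite::write_json(cfg, file, auto_unbox = TRUE, digits = NA)
  }
  invisible(cfg)
}

#' Rebuild parameters and model spec from a flat configuration
#'
#' @param cfg a flat named list as produced by [model_to_config()], or a
#'   path to a YAML/JSON file holding one.
#' @return A list with elements `params` ([kinetic_parameters()]) and
#'   `spec` ([model_spec()]).
#' @export
config_to_model <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1L) {
    cfg <- read_flat_config(cfg)
  }
  par_args <- cfg[intersect(.param_fields, names(cfg))]
  params <- do.call(kinetic_parameters, par_args)
  hill <- hill_spec(K = cfg$hill_K %||% 0.5, n = cfg$hill_n %||% 1.5)
  spec <- model_spec(kinetics = cfg$kinetics %||% "mass_action",
                     feedback_logic = cfg$feedback_logic %||% "none",
                     hill = hill)
  list(params = params, spec = spec)
}

read_flat_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
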
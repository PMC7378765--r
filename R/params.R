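# Parameter container, validation and derived scalar quantities.

# The 13 model scalars, in canonical order.
PARAM_NAMES <- c("CG1", "CG2", "RG", "alpha", "beta", "lambda",
                 "RV1", "RV2", "FV1", "FV2", "CV", "pi", "psi")

verr <- function(msg) {
  stop(errorCondition(msg, class = c("vaxgame_validation_error", "error",
                                     "condition")))
}

ierr <- function(msg) {
  stop(errorCondition(msg, class = c("vaxgame_integration_error", "error",
                                     "condition")))
}

#' Construct a game parameter set
#'
#' Bundles the 13 scalars of the regulator-manufacturer game.  Defaults are
#' the baseline calibration used throughout the simulation experiments.
#' Hard structural constraints (see [validate_params()]) are enforced at
#' construction; soft ones (the penalty coefficient `FV1/RV2 > 1`) only
#' produce entries in the validation report, never an error, because the
#' baseline calibration itself violates them.
#'
#' @param CG1 base cost of active supervision (> 0, payoff units).
#' @param CG2 base cost of passive supervision (> 0, payoff units).
#' @param RG government benefit from uncovering a non-self-disciplined
#'   manufacturer (>= 0).
#' @param alpha detection probability of active supervision, in (0, 1].
#' @param beta detection probability of passive supervision, in (0, 1];
#'   must exceed `alpha`.
#' @param lambda probability that a non-self-disciplined manufacturer is
#'   reported by a third party, in \[0, 1\].
#' @param RV1 manufacturer revenue under self-discipline.
#' @param RV2 manufacturer revenue under non-self-discipline; must exceed
#'   `RV1`.
#' @param FV1 fine plus reputation loss when non-self-discipline is
#'   detected (>= 0).
#' @param FV2 rectification and disposal cost after detection (>= 0).
#' @param CV manufacturer's cost of cooperating with an inspection (>= 0).
#' @param pi strictness coefficient of government power and regulations
#'   (> 0); a stricter government lowers the effective active-supervision
#'   cost `CG1/pi`.
#' @param psi coefficient of public awareness / exposure of government
#'   corruption (> 0); lowers the effective passive-supervision cost
#'   `CG2/psi`.
#' @param validate if `TRUE` (default), hard invariant violations raise an
#'   error.
#' @return An object of class `game_params`: a named list of the 13
#'   scalars.
#' @examples
#' p <- game_params()           # baseline calibration
#' p2 <- game_params(FV1 = 10)  # heavier fine, rest at baseline
#' @export
game_params <- function(CG1 = 1, CG2 = 5, RG = 3, alpha = 0.3, beta = 0.8,
                        lambda = 0.4, RV1 = 2, RV2 = 6, FV1 = 4, FV2 = 2,
                        CV = 1, pi = 1, psi = 1, validate = TRUE) {
  p <- list(CG1 = CG1, CG2 = CG2, RG = RG, alpha = alpha, beta = beta,
            lambda = lambda, RV1 = RV1, RV2 = RV2, FV1 = FV1, FV2 = FV2,
            CV = CV, pi = pi, psi = psi)
  bad <- !vapply(p, function(v) is.numeric(v) && length(v) == 1L, logical(1))
  if (any(bad)) {
    verr(paste0("parameters must be numeric scalars: ",
                paste(names(p)[bad], collapse = ", ")))
  }
  p <- lapply(p, as.numeric)
  class(p) <- "game_params"
  if (validate) {
    rep <- validate_params(p)
    if (length(rep$errors)) {
      verr(paste0("invalid parameters:\n  ",
                  paste(rep$errors, collapse = "\n  ")))
    }
  }
  p
}

#' Baseline parameter calibration
#'
#' The reference calibration used by the simulation experiments:
#' `CG1 = 1, CG2 = 5, RG = 3, alpha = 0.3, beta = 0.8, lambda = 0.4,
#' RV1 = 2, RV2 = 6, FV1 = 4, FV2 = 2, CV = 1, pi = 1, psi = 1`.
#'
#' @return A `game_params` object.
#' @export
baseline_params <- function() game_params()

#' Validate a parameter set
#'
#' Checks the structural constraints of the model and returns a report
#' rather than raising.  Hard constraints (violations are errors):
#' all values finite; costs and coefficients positive where required;
#' `0 < alpha < beta <= 1`; `lambda` in \[0, 1\]; `RV2 > RV1` (the
#' temptation must be real); effective costs ordered
#' `CG2/psi > CG1/pi > 0` (reactive supervision is dearer per case).
#' Soft constraint (violation is a warning entry): penalty coefficient
#' `mu = FV1/RV2 > 1`, i.e. the fine should exceed the illicit revenue for
#' supervision to have teeth.  The baseline calibration itself has
#' `mu = 4/6 < 1`, so this is deliberately not fatal.
#'
#' @param params a `game_params` object (or plain named list of the 13
#'   scalars).
#' @return An object of class `validation_report`: list with character
#'   vectors `errors` and `warnings` and logical `valid`
#'   (`TRUE` iff no errors).
#' @examples
#' validate_params(baseline_params())          # one warning, no errors
#' @export
validate_params <- function(params) {
  p <- params
  errors <- character()
  warnings <- character()
  vals <- unlist(p[PARAM_NAMES])
  if (anyNA(vals) || any(!is.finite(vals))) {
    errors <- c(errors, "all parameters must be finite numbers")
    rep <- list(errors = errors, warnings = warnings, valid = FALSE)
    class(rep) <- "validation_report"
    return(rep)
  }
  chk <- function(cond, msg) if (!cond) errors <<- c(errors, msg)
  chk(p$CG1 > 0, "CG1 must be > 0")
  chk(p$CG2 > 0, "CG2 must be > 0")
  chk(p$RG >= 0, "RG must be >= 0")
  chk(p$FV1 >= 0, "FV1 must be >= 0")
  chk(p$FV2 >= 0, "FV2 must be >= 0")
  chk(p$CV >= 0, "CV must be >= 0")
  chk(p$pi > 0, "pi must be > 0")
  chk(p$psi > 0, "psi must be > 0")
  chk(p$alpha > 0 && p$alpha <= 1, "alpha must be in (0, 1]")
  chk(p$beta > 0 && p$beta <= 1, "beta must be in (0, 1]")
  chk(p$alpha < p$beta, "alpha must be < beta")
  chk(p$lambda >= 0 && p$lambda <= 1, "lambda must be in [0, 1]")
  chk(p$RV2 > p$RV1, "RV2 must exceed RV1")
  if (p$pi > 0 && p$psi > 0) {
    chk(p$CG2 / p$psi > p$CG1 / p$pi,
        "effective passive cost CG2/psi must exceed active cost CG1/pi")
  }
  if (p$RV2 > 0 && p$FV1 / p$RV2 <= 1) {
    warnings <- c(warnings, sprintf(
      "penalty coefficient mu = FV1/RV2 = %.4g <= 1: the fine does not exceed the illicit revenue, so punishment is a weak deterrent",
      p$FV1 / p$RV2))
  }
  rep <- list(errors = errors, warnings = warnings,
              valid = length(errors) == 0L)
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat("parameter validation:", if (x$valid) "valid" else "INVALID", "\n")
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @export
print.game_params <- function(x, ...) {
  cat("game parameters:\n")
  v <- unlist(x[PARAM_NAMES])
  cat(paste0("  ", format(PARAM_NAMES, width = 6), " = ",
             formatC(v, digits = 10, format = "g"), collapse = "\n"), "\n")
  invisible(x)
}

#' Effective supervision costs
#'
#' The cost actually borne by the regulator per episode: active
#' supervision costs `CG1/pi` (stricter regulations, cheaper proactive
#' inspection) and passive supervision costs `CG2/psi` (more public
#' awareness, cheaper reactive response).
#'
#' @param params a `game_params` object.
#' @return Named numeric vector `c(active = CG1/pi, passive = CG2/psi)`.
#' @export
effective_costs <- function(params) {
  if (params$pi == 0 || params$psi == 0) verr("pi and psi must be nonzero")
  c(active = params$CG1 / params$pi, passive = params$CG2 / params$psi)
}

#' Derived scalar quantities
#'
#' Computes the dimensionless quantities that organise the dynamics:
#' \describe{
#'   \item{epsilon}{profit-loss ratio of non-self-discipline,
#'     `(RV2 - RV1) / (RV2 + FV1 + FV2)`: the excess revenue of cheating
#'     relative to what is forfeited when caught.  Its ordering against
#'     `alpha` and `beta * lambda` selects the dynamic regime.}
#'   \item{mu}{penalty coefficient `FV1 / RV2`.}
#'   \item{active_cost, passive_cost}{the effective costs `CG1/pi`,
#'     `CG2/psi`.}
#'   \item{beta_lambda}{`beta * lambda`, the detection probability of the
#'     passive channel (report, then successful inspection).}
#' }
#'
#' @param params a `game_params` object.
#' @return Object of class `derived_quantities` (named list).
#' @examples
#' derived_quantities(baseline_params())$epsilon  # 1/3
#' @export
derived_quantities <- function(params) {
  p <- params
  S <- p$RV2 + p$FV1 + p$FV2
  if (S == 0) verr("RV2 + FV1 + FV2 must be nonzero")
  ec <- effective_costs(p)
  out <- list(epsilon = (p$RV2 - p$RV1) / S,
              mu = p$FV1 / p$RV2,
              active_cost = unname(ec["active"]),
              passive_cost = unname(ec["passive"]),
              beta_lambda = p$beta * p$lambda)
  class(out) <- "derived_quantities"
  out
}

#' @export
print.derived_quantities <- function(x, ...) {
  cat(sprintf(
    "epsilon = %.6g, mu = %.6g, beta*lambda = %.6g, costs (active %.6g, passive %.6g)\n",
    x$epsilon, x$mu, x$beta_lambda, x$active_cost, x$passive_cost))
  invisible(x)
}

# Replace named fields of a parameter set, re-validating hard constraints.
# Used by sweeps and the CLI; exported for convenience.

#' Modify a parameter set
#'
#' @param params a `game_params` object.
#' @param ... named scalar replacements, e.g. `FV1 = 10`.
#' @param validate raise on hard invariant violations (default `TRUE`).
#' @return A new `game_params` object.
#' @export
update_params <- function(params, ..., validate = TRUE) {
  repl <- list(...)
  if (length(repl) == 0L) return(params)
  unknown <- setdiff(names(repl), PARAM_NAMES)
  if (length(unknown)) {
    verr(paste0("unknown parameter ", paste(unknown, collapse = ", ")))
  }
  p <- unclass(params)
  p[names(repl)] <- lapply(repl, as.numeric)
  do.call(game_params, c(p, list(validate = validate)))
}
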
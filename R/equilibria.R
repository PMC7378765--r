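# Equilibrium enumeration, Jacobian-based stability, regime classification.

#' Enumerate equilibria of the replicator system
#'
#' The four corners of the unit square are always rest points of the
#' planar replicator system.  In addition there may be one interior
#' (mixed-strategy) rest point where both payoff-difference brackets
#' vanish:
#' \deqn{x^* = 1 - \frac{\lambda CG2/\psi - CG1/\pi}{(\beta\lambda - \alpha) RG},
#'       \qquad
#'       y^* = \frac{RV1 - RV2 + \beta\lambda (RV2 + FV1 + FV2)}
#'                  {(RV2 + FV1 + FV2)(\beta\lambda - \alpha)},}
#' included only when both coordinates lie strictly inside (0, 1).  When
#' `beta * lambda == alpha` the two inspection channels are equally
#' effective in expectation, the denominators vanish and the interior
#' point is reported absent with a `degenerate` flag.
#'
#' @param params a `game_params` object.
#' @return List of class `equilibrium_set`: elements are unlabelled
#'   `equilibrium_report` skeletons (fields `point`, `kind`); attributes
#'   `interior_candidate` (the raw `(x*, y*)`, or `NULL`) and `degenerate`.
#' @examples
#' length(find_equilibria(baseline_params()))  # 4: corners only
#' @export
find_equilibria <- function(params) {
  p <- params
  reports <- lapply(list(c(0, 0), c(0, 1), c(1, 0), c(1, 1)), function(pt) {
    structure(list(point = c(x = pt[1], y = pt[2]), kind = "pure",
                   jacobian = NULL, label = NA_character_),
              class = "equilibrium_report")
  })
  br <- replicator_brackets(params)
  denom <- br$bl - p$alpha
  degenerate <- abs(denom) < 1e-12
  candidate <- NULL
  if (!degenerate && p$RG > 0) {
    ec <- effective_costs(p)
    x_star <- 1 - (p$lambda * ec[["passive"]] - ec[["active"]]) /
      (denom * p$RG)
    y_star <- (p$RV1 - p$RV2 + br$bl * br$S) / (br$S * denom)
    candidate <- c(x = x_star, y = y_star)
    if (x_star > 0 && x_star < 1 && y_star > 0 && y_star < 1) {
      reports <- c(reports, list(structure(
        list(point = candidate, kind = "interior", jacobian = NULL,
             label = NA_character_),
        class = "equilibrium_report")))
    }
  }
  structure(reports, class = "equilibrium_set",
            interior_candidate = candidate, degenerate = degenerate)
}

#' Jacobian entries of the replicator system at a point
#'
#' Partial derivatives of `(dx/dt, dy/dt)` with respect to `(x, y)`.
#' At the four corners the off-diagonal entries vanish identically, so
#' corner stability is read off the two diagonal entries; at the interior
#' rest point both diagonal entries vanish (both brackets are zero there),
#' forcing a zero trace.
#'
#' @param params a `game_params` object.
#' @param x,y evaluation point in \[0, 1\]^2.
#' @return Named list `a11`, `a12`, `a21`, `a22` plus `det` and `trace`,
#'   class `jacobian_entries`.
#' @export
jacobian_entries <- function(params, x, y) {
  check_state(x, y)
  p <- params
  br <- replicator_brackets(params)
  a11 <- (1 - 2 * x) * br$manufacturer(y)
  a12 <- x * (1 - x) * br$S * (p$alpha - br$bl)
  a21 <- y * (1 - y) * (br$bl - p$alpha) * p$RG
  a22 <- (1 - 2 * y) * br$government(x)
  structure(list(a11 = a11, a12 = a12, a21 = a21, a22 = a22,
                 det = a11 * a22 - a12 * a21, trace = a11 + a22),
            class = "jacobian_entries")
}

#' @export
print.jacobian_entries <- function(x, ...) {
  cat(sprintf("Jacobian: [%.6g %.6g; %.6g %.6g], det %.6g, trace %.6g\n",
              x$a11, x$a12, x$a21, x$a22, x$det, x$trace))
  invisible(x)
}

#' Classify the stability of one equilibrium
#'
#' Linear stability via the trace/determinant of the Jacobian:
#' an equilibrium is an ESS (locally asymptotically stable) iff
#' `tr J < 0` and `det J > 0`; a saddle iff `det J < 0`; unstable iff
#' `tr J > 0` and `det J > 0`.  An interior rest point with
#' `|tr J| < tol` and `det J > 0` is a centre (pure imaginary
#' eigenvalues, closed orbits around it — stable but not asymptotically
#' stable).  Any decisive quantity within `tol` of zero at a corner is
#' reported `non-hyperbolic` rather than silently assigned.
#'
#' @param params a `game_params` object.
#' @param report an `equilibrium_report` from [find_equilibria()].
#' @param tol tie tolerance on decisive quantities (default 1e-9).
#' @return The report with `jacobian` and `label` filled in.
#' @export
classify_equilibrium <- function(params, report, tol = 1e-9) {
  J <- jacobian_entries(params, report$point[1], report$point[2])
  report$jacobian <- J
  tr <- J$trace; dt <- J$det
  label <-
    if (report$kind == "interior" && abs(tr) < tol && dt > tol) "center"
    else if (dt < -tol) "saddle"
    else if (tr < -tol && dt > tol) "ESS"
    else if (tr > tol && dt > tol) "unstable"
    else "non-hyperbolic"
  report$label <- label
  report
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat(sprintf("equilibrium (%.6g, %.6g) [%s]%s\n", x$point[1], x$point[2],
              x$kind,
              if (is.na(x$label)) "" else paste0(": ", x$label)))
  if (!is.null(x$jacobian)) print(x$jacobian)
  invisible(x)
}

#' Find and classify all equilibria
#'
#' Convenience wrapper: [find_equilibria()] followed by
#' [classify_equilibrium()] on each rest point.
#'
#' @inheritParams classify_equilibrium
#' @return An `equilibrium_set` with all labels filled.
#' @export
equilibrium_analysis <- function(params, tol = 1e-9) {
  eqs <- find_equilibria(params)
  out <- lapply(eqs, classify_equilibrium, params = params, tol = tol)
  attributes(out) <- attributes(eqs)
  out
}

#' @export
print.equilibrium_set <- function(x, ...) {
  cat(sprintf("equilibrium set: %d rest points%s\n", length(x),
              if (isTRUE(attr(x, "degenerate"))) " (degenerate interior)"
              else ""))
  for (r in x) print(r)
  invisible(x)
}

# Stable corners by direct sign analysis of the two diagonal Jacobian
# entries (off-diagonals vanish at corners).
stable_corners <- function(params, tol = 1e-9) {
  eqs <- equilibrium_analysis(params, tol = tol)
  pure <- Filter(function(r) r$kind == "pure", eqs)
  ess <- Filter(function(r) identical(r$label, "ESS"), pure)
  lapply(ess, function(r) unname(r$point))
}

#' Classify the parameter regime
#'
#' The dynamic regime is set by the ordering of the profit-loss ratio
#' `epsilon = (RV2 - RV1)/(RV2 + FV1 + FV2)` against the two detection
#' probabilities `alpha` (active channel) and `beta * lambda` (passive
#' channel), together with the sign of the regulator's cost comparison
#' `lambda * CG2/psi` versus `CG1/pi`.  Enumerated cases:
#' \describe{
#'   \item{cycle_case}{`alpha > epsilon > beta*lambda > 0` or
#'     `0 < alpha < epsilon < beta*lambda`: no ESS, closed orbits around
#'     the interior centre (the transition period of the game).}
#'   \item{case2_00 / case2_10}{`epsilon > beta*lambda > alpha > 0` /
#'     `0 < epsilon < beta*lambda < alpha`, each with
#'     `lambda*CG2/psi < CG1/pi`: ESS at (0,0) / (1,0).}
#'   \item{case3_01 / case3_11}{`epsilon > alpha > beta*lambda > 0` /
#'     `0 < epsilon < alpha < beta*lambda`, each with
#'     `CG1/pi < lambda*CG2/psi`: ESS at (0,1) / (1,1).}
#' }
#' Parameter sets matching none of these (the baseline calibration is
#' one: its ordering pairs with the "wrong" cost sign) are labelled
#' `outside_enumerated`, and exact ties on any decisive quantity are
#' labelled `critical`.  Direct corner sign analysis is always run as
#' well, so the report carries both the case prediction and the stable
#' corners the Jacobian actually certifies, with a flag when the two
#' disagree.
#'
#' @param params a `game_params` object.
#' @param tol tie tolerance on the decisive quantities (default 1e-9).
#' @return Object of class `regime_classification`: list with `case_id`,
#'   `ordering` (human-readable ordering string), `epsilon`, `alpha`,
#'   `beta_lambda`, `cost_comparison` (sign of
#'   `lambda*CG2/psi - CG1/pi`), `predicted_ess` (from the enumerated
#'   case, `NULL` in the cycle case or when outside), `sign_analysis_ess`
#'   (list of stable corners by Jacobian signs), and `agreement`.
#' @export
classify_regime <- function(params, tol = 1e-9) {
  dq <- derived_quantities(params)
  eps <- dq$epsilon; a <- params$alpha; bl <- dq$beta_lambda
  cost_diff <- params$lambda * dq$passive_cost - dq$active_cost

  tie <- min(abs(eps - a), abs(eps - bl), abs(a - bl), abs(cost_diff)) < tol

  case_id <- "outside_enumerated"
  predicted <- NULL
  if (tie) {
    case_id <- "critical"
  } else if ((a > eps && eps > bl && bl > 0) || (a > 0 && a < eps && eps < bl)) {
    case_id <- "cycle_case"
  } else if (eps > bl && bl > a && a > 0 && cost_diff < 0) {
    case_id <- "case2_00"; predicted <- c(0, 0)
  } else if (eps > 0 && eps < bl && bl < a && cost_diff < 0) {
    case_id <- "case2_10"; predicted <- c(1, 0)
  } else if (eps > a && a > bl && bl > 0 && cost_diff > 0) {
    case_id <- "case3_01"; predicted <- c(0, 1)
  } else if (eps > 0 && eps < a && a < bl && cost_diff > 0) {
    case_id <- "case3_11"; predicted <- c(1, 1)
  }

  vals <- c(epsilon = eps, alpha = a, `beta*lambda` = bl)
  ord <- names(sort(vals, decreasing = TRUE))
  ordering <- paste(ord, collapse = " > ")

  sign_ess <- stable_corners(params, tol = tol)
  agreement <- if (is.null(predicted)) {
    if (case_id == "cycle_case") length(sign_ess) == 0L else NA
  } else {
    length(sign_ess) == 1L && isTRUE(all.equal(sign_ess[[1]], predicted))
  }

  structure(list(case_id = case_id, ordering = ordering, epsilon = eps,
                 alpha = a, beta_lambda = bl, cost_comparison = sign(cost_diff),
                 cost_difference = cost_diff, predicted_ess = predicted,
                 sign_analysis_ess = sign_ess, agreement = agreement),
            class = "regime_classification")
}

#' @export
print.regime_classification <- function(x, ...) {
  cat(sprintf("regime: %s (%s; lambda*CG2/psi %s CG1/pi)\n", x$case_id,
              x$ordering,
              if (x$cost_comparison > 0) ">" else if (x$cost_comparison < 0) "<" else "="))
  if (!is.null(x$predicted_ess)) {
    cat(sprintf("  case-predicted ESS: (%g, %g)\n",
                x$predicted_ess[1], x$predicted_ess[2]))
  }
  if (length(x$sign_analysis_ess)) {
    cat("  sign-analysis ESS:",
        paste(vapply(x$sign_analysis_ess,
                     function(p) sprintf("(%g, %g)", p[1], p[2]),
                     character(1)), collapse = ", "), "\n")
  } else cat("  sign-analysis ESS: none\n")
  invisible(x)
}

#' Check a claimed stable point against the Jacobian sign analysis
#'
#' Diagnostic for narrative claims about where the system settles.  Under
#' the baseline calibration the published simulation narrative asserts
#' convergence to (0,0) (non-self-discipline, passive supervision), yet
#' the Jacobian sign conditions make (0,0) a saddle and certify (0,1) as
#' the unique ESS; long integration confirms (0,1).  This function makes
#' such conflicts explicit instead of papering over them.
#'
#' @param params a `game_params` object.
#' @param claim length-2 corner claimed to be the stable point
#'   (default `c(0, 0)`).
#' @param tol tie tolerance passed to the classifier.
#' @return List with the claim, its stability label, the corners actually
#'   certified stable, logical `conflict`, and a message.
#' @export
check_claimed_ess <- function(params, claim = c(0, 0), tol = 1e-9) {
  if (!all(claim %in% c(0, 1))) verr("claim must be a corner of [0,1]^2")
  rep <- classify_equilibrium(params, structure(
    list(point = c(x = claim[1], y = claim[2]), kind = "pure",
         jacobian = NULL, label = NA_character_),
    class = "equilibrium_report"), tol = tol)
  stable <- stable_corners(params, tol = tol)
  claim_is_stable <- identical(rep$label, "ESS")
  conflict <- !claim_is_stable
  msg <- if (conflict) {
    sprintf(
      "claimed stable point (%g, %g) is a %s under the Jacobian sign conditions; certified stable corner(s): %s",
      claim[1], claim[2], rep$label,
      if (length(stable)) paste(vapply(stable, function(p)
        sprintf("(%g, %g)", p[1], p[2]), character(1)), collapse = ", ")
      else "none")
  } else {
    sprintf("claimed stable point (%g, %g) is confirmed as an ESS",
            claim[1], claim[2])
  }
  list(claim = claim, claim_label = rep$label,
       sign_analysis_ess = stable, conflict = conflict, message = msg)
}

# JSON-friendly view of an equilibrium set / regime report (10 significant
# digits, stable field order) used by the CLI.
equilibrium_set_json <- function(eqs) {
  lapply(unclass(eqs), function(r) {
    list(point = list(x = r$point[[1]], y = r$point[[2]]),
         kind = r$kind,
         jacobian = if (is.null(r$jacobian)) NULL else
           r$jacobian[c("a11", "a12", "a21", "a22", "det", "trace")],
         label = r$label)
  })
}

regime_json <- function(reg) {
  list(case_id = reg$case_id, ordering = reg$ordering,
       epsilon = reg$epsilon, alpha = reg$alpha,
       beta_lambda = reg$beta_lambda,
       cost_comparison = reg$cost_comparison,
       cost_difference = reg$cost_difference,
       predicted_ess = reg$predicted_ess,
       sign_analysis_ess = lapply(reg$sign_analysis_ess, function(p)
         list(x = p[1], y = p[2])),
       agreement = reg$agreement)
}
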
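# Simulation experiments: phase portraits, parameter sweeps, the critical
# fine, and a constrained parameter sampler for property tests.

#' Phase portrait from a grid of initial states
#'
#' Integrates one trajectory per initial state and classifies each
#' long-run outcome, tallying labels across the grid — the programmatic
#' equivalent of reading a phase portrait.
#'
#' @param params a `game_params` object.
#' @param starts two-column matrix/data.frame of initial states, or
#'   `NULL` for the default 5 x 5 uniform interior grid
#'   (`seq(1/6, 5/6, length.out = 5)` in each coordinate).
#' @param horizon,n_out passed to [integrate_trajectory()].
#' @param tol vertex tolerance passed to [detect_long_run_behavior()].
#' @return Object of class `phase_portrait`: list with `starts`,
#'   `trajectories`, `outcomes`, and `tally` (table of outcome labels).
#' @export
run_baseline <- function(params, starts = NULL, horizon = 500,
                         n_out = 2001, tol = 1e-3) {
  if (is.null(starts)) {
    g <- seq(1 / 6, 5 / 6, length.out = 5)
    starts <- as.matrix(expand.grid(x = g, y = g))
  }
  starts <- as.matrix(starts)
  if (ncol(starts) != 2L) verr("starts must have two columns (x, y)")
  trajectories <- vector("list", nrow(starts))
  outcomes <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    tr <- integrate_trajectory(params, starts[i, ], horizon = horizon,
                               n_out = n_out)
    trajectories[[i]] <- tr
    outcomes[[i]] <- detect_long_run_behavior(tr, tol = tol)
  }
  labels <- vapply(outcomes, `[[`, character(1), "label")
  structure(list(starts = starts, trajectories = trajectories,
                 outcomes = outcomes, tally = table(labels)),
            class = "phase_portrait")
}

#' @export
print.phase_portrait <- function(x, ...) {
  cat(sprintf("phase portrait: %d starts\n", nrow(x$starts)))
  print(x$tally)
  invisible(x)
}

#' Sweep one parameter
#'
#' Re-runs regime classification and a single long-run simulation (from a
#' common initial state) for each value of one parameter, all other
#' parameters held fixed.  Values violating hard invariants are marked
#' invalid and skipped rather than aborting the sweep.
#'
#' @param params a `game_params` base set.
#' @param name name of the swept parameter (one of the 13).
#' @param values numeric vector of values, strictly monotone.
#' @param init common initial state (default `c(0.5, 0.5)`, the
#'   uninformative midpoint).
#' @param horizon,n_out integration controls.
#' @param tol vertex tolerance for outcome detection.
#' @return Object of class `sweep_result`: the swept name, and a
#'   `data.frame` `table` with one row per value: `value`, `valid`,
#'   `case_id`, `outcome`, `terminal_x`, `terminal_y`, `epsilon`.
#' @export
sweep_parameter <- function(params, name, values, init = c(0.5, 0.5),
                            horizon = 500, n_out = 2001, tol = 1e-3) {
  if (!name %in% PARAM_NAMES) verr(paste0("unknown parameter ", name))
  if (length(values) > 1 && !(all(diff(values) > 0) || all(diff(values) < 0))) {
    verr("sweep values must be strictly monotone")
  }
  rows <- lapply(values, function(v) {
    args <- stats::setNames(list(v), name)
    pv <- try(do.call(update_params, c(list(params), args)), silent = TRUE)
    if (inherits(pv, "try-error")) {
      return(data.frame(value = v, valid = FALSE, case_id = NA_character_,
                        outcome = NA_character_, terminal_x = NA_real_,
                        terminal_y = NA_real_, epsilon = NA_real_))
    }
    reg <- classify_regime(pv)
    tr <- integrate_trajectory(pv, init, horizon = horizon, n_out = n_out)
    oc <- detect_long_run_behavior(tr, tol = tol)
    data.frame(value = v, valid = TRUE, case_id = reg$case_id,
               outcome = oc$label,
               terminal_x = oc$terminal_state[[1]],
               terminal_y = oc$terminal_state[[2]],
               epsilon = reg$epsilon)
  })
  structure(list(swept_parameter = name, init = init,
                 table = do.call(rbind, rows)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep over %s from (%g, %g):\n", x$swept_parameter,
              x$init[1], x$init[2]))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write a sweep result as CSV
#'
#' One row per swept value: `value,case_id,outcome,terminal_x,terminal_y`.
#'
#' @param sweep a `sweep_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  tb <- sweep$table
  # labels such as vertex(0,1) contain commas, so string fields are quoted
  lines <- c("value,case_id,outcome,terminal_x,terminal_y",
             sprintf("%.10g,\"%s\",\"%s\",%.10g,%.10g", tb$value, tb$case_id,
                     tb$outcome, tb$terminal_x, tb$terminal_y))
  writeLines(lines, path)
  invisible(path)
}

#' Critical fine at which punishment starts to deter
#'
#' Finds, by bisection, the fine `FV1` at which the profit-loss ratio
#' `epsilon(FV1) = (RV2 - RV1)/(RV2 + FV1 + FV2)` crosses the
#' passive-channel detection probability `beta * lambda` — the boundary
#' where increasing punishment tips the manufacturer population from the
#' non-self-discipline regime into the transition (and, beyond a second
#' crossing at `epsilon = alpha`, the self-discipline) regime.  The
#' closed form \deqn{FV1^* = (RV2 - RV1)/(\beta\lambda) - RV2 - FV2}
#' is reported alongside as a cross-check.  Under the baseline
#' calibration the crossing sits at `FV1 = 4.5`.
#'
#' @param params a `game_params` object (its own `FV1` is ignored).
#' @param bracket length-2 interval of `FV1` values to search
#'   (default `c(0, 20)`).
#' @param tol bisection half-width target (default 1e-6).
#' @return Object of class `threshold_result`: `parameter`,
#'   `critical_value` (bisection), `closed_form`, `bracket`, `iterations`
#'   and a `criterion` description.
#' @examples
#' find_critical_fine(baseline_params())$critical_value  # 4.5
#' @export
find_critical_fine <- function(params, bracket = c(0, 20), tol = 1e-6) {
  if (length(bracket) != 2L || bracket[1] >= bracket[2]) {
    verr("bracket must be an increasing length-2 interval")
  }
  bl <- params$beta * params$lambda
  crit <- function(fv1) {
    (params$RV2 - params$RV1) / (params$RV2 + fv1 + params$FV2) - bl
  }
  lo <- bracket[1]; hi <- bracket[2]
  flo <- crit(lo); fhi <- crit(hi)
  if (flo == 0) { hi <- lo; fhi <- flo }
  else if (fhi == 0) { lo <- hi; flo <- fhi }
  else if (sign(flo) == sign(fhi)) {
    verr(sprintf(
      "no crossing of epsilon(FV1) = beta*lambda in [%g, %g]",
      bracket[1], bracket[2]))
  }
  iter <- 0L
  while (hi - lo > tol && iter < 200L) {
    mid <- (lo + hi) / 2
    fm <- crit(mid)
    if (fm == 0) { lo <- mid; hi <- mid; break }
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    iter <- iter + 1L
  }
  closed <- if (bl > 0) {
    (params$RV2 - params$RV1) / bl - params$RV2 - params$FV2
  } else NA_real_
  structure(list(parameter = "FV1", critical_value = (lo + hi) / 2,
                 closed_form = closed, bracket = bracket,
                 iterations = iter,
                 criterion = "sign change of epsilon(FV1) - beta*lambda"),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "critical %s = %.8g (bisection, %d iters; closed form %.8g)\n",
    x$parameter, x$critical_value, x$iterations, x$closed_form))
  invisible(x)
}

#' Sample valid parameter sets
#'
#' Rejection sampler over baseline-scale ranges, producing parameter sets
#' that satisfy every hard invariant; optionally also `mu > 1` and/or a
#' requested dynamic regime (see [classify_regime()]).  Deterministic for
#' a fixed seed.  Ranges: `CG1` in (0.5, 2.5), `pi`, `psi` in (0.5, 2),
#' `CG2` in (0.5, 8) subject to the cost ordering, `RG` in (0.5, 10),
#' `alpha` in (0.05, 0.9), `beta` in (`alpha`, 1), `lambda` in
#' (0.05, 0.95), `RV1` in (0.5, 4), `RV2 - RV1` in (0.5, 8), `FV1` in
#' (0, 12) (or (`RV2`, `2 RV2`) under the `mu` constraint), `FV2` in
#' (0, 4), `CV` in (0, 2).
#'
#' @param seed integer RNG seed.
#' @param n number of sets to return (> 0).
#' @param case optional `case_id` the sets must fall in (one of
#'   `cycle_case`, `case2_00`, `case2_10`, `case3_01`, `case3_11`).
#' @param require_mu_gt_1 require the penalty coefficient to exceed 1.
#' @param max_tries rejection budget per returned set (default 10000).
#' @return List of `n` `game_params` objects.
#' @export
sample_parameters <- function(seed, n, case = NULL, require_mu_gt_1 = FALSE,
                              max_tries = 10000L) {
  if (n <= 0) verr("n must be > 0")
  if (!is.null(case) &&
      !case %in% c("cycle_case", "case2_00", "case2_10", "case3_01",
                   "case3_11")) {
    verr(paste0("unknown case constraint ", case))
  }
  set.seed(as.integer(seed))
  runif1 <- function(lo, hi) stats::runif(1, lo, hi)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    found <- FALSE
    for (try_i in seq_len(max_tries)) {
      alpha <- runif1(0.05, 0.9)
      beta <- runif1(alpha + 0.01, 1)
      lambda <- runif1(0.05, 0.95)
      pi_ <- runif1(0.5, 2); psi <- runif1(0.5, 2)
      CG1 <- runif1(0.5, 2.5)
      CG2 <- runif1(0.5, 8)
      RG <- runif1(0.5, 10)
      RV1 <- runif1(0.5, 4)
      RV2 <- RV1 + runif1(0.5, 8)
      FV1 <- if (require_mu_gt_1) runif1(RV2 * 1.001, 2 * RV2)
             else runif1(0, 12)
      FV2 <- runif1(0, 4)
      CV <- runif1(0, 2)
      p <- try(game_params(CG1 = CG1, CG2 = CG2, RG = RG, alpha = alpha,
                           beta = beta, lambda = lambda, RV1 = RV1,
                           RV2 = RV2, FV1 = FV1, FV2 = FV2, CV = CV,
                           pi = pi_, psi = psi), silent = TRUE)
      if (inherits(p, "try-error")) next
      if (!is.null(case)) {
        if (classify_regime(p)$case_id != case) next
        # the closed-orbit regime additionally needs the interior centre
        # to sit inside the square; the ordering alone does not ensure it
        if (case == "cycle_case" && length(find_equilibria(p)) != 5L) next
      }
      out[[i]] <- p
      found <- TRUE
      break
    }
    if (!found) {
      verr(sprintf(
        "rejection budget (%d tries) exhausted for the requested constraints",
        max_tries))
    }
  }
  out
}
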
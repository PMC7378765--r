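# Replicator vector field on the unit square and trajectory integration.

# Closed-form brackets of the two replicator equations.  The manufacturer
# bracket is E11 - E12 as a function of y; the government bracket is
# E21 - E22 as a function of x.  Kept internal: everything downstream
# (vector field, Jacobian, interior equilibrium) is built from these two.
replicator_brackets <- function(params) {
  p <- params
  S <- p$RV2 + p$FV1 + p$FV2
  bl <- p$beta * p$lambda
  ec <- effective_costs(p)
  list(
    manufacturer = function(y) y * S * (p$alpha - bl) + p$RV1 - p$RV2 + bl * S,
    government = function(x) (p$alpha - bl) * p$RG * (1 - x) +
      p$lambda * ec[["passive"]] - ec[["active"]],
    S = S, bl = bl)
}

#' Replicator vector field
#'
#' The coupled replicator equations of the two populations:
#' `dx/dt = x (1 - x) (E11 - E12)` and `dy/dt = y (1 - y) (E21 - E22)`,
#' with the payoff differences in closed form.  A strategy's share grows
#' in proportion to its payoff advantage over the population average.
#'
#' @param params a `game_params` object.
#' @param x,y population state in \[0, 1\]^2.
#' @return Named numeric vector `c(dx, dy)`.
#' @examples
#' vector_field(baseline_params(), 0.5, 0.5)  # c(-0.07, 0.2425)
#' @export
vector_field <- function(params, x, y) {
  x <- unname(x); y <- unname(y)
  check_state(x, y)
  br <- replicator_brackets(params)
  c(dx = x * (1 - x) * br$manufacturer(y),
    dy = y * (1 - y) * br$government(x))
}

#' Integrate a replicator trajectory
#'
#' Solves the planar replicator system forward in (dimensionless) time
#' with an adaptive solver (`deSolve::ode`).  The unit square is
#' forward-invariant for the exact flow; numerically, states that drift
#' outside by less than `clamp_tol` are projected back, and larger
#' excursions abort with an integration error.
#'
#' @param params a `game_params` object.
#' @param init numeric length-2 initial state `c(x, y)` in \[0, 1\]^2.
#' @param horizon integration horizon (> 0); default 500 time units,
#'   enough for the stiffest baseline-scale dynamics to settle and for
#'   several revolutions of typical closed orbits.
#' @param n_out number of equally spaced output times (>= 2).
#' @param rtol,atol relative/absolute solver tolerances.
#' @param method `deSolve` integrator name; the default `lsode` handles
#'   both the stiff exponential collapse onto a corner and the smooth
#'   closed orbits of the centre regime.
#' @param clamp_tol maximal tolerated excursion outside the unit square.
#' @return Object of class `game_trajectory`: a `data.frame` with columns
#'   `t`, `x`, `y` and the parameter set in attribute `"params"`.
#' @export
integrate_trajectory <- function(params, init, horizon = 500, n_out = 2001,
                                 rtol = 1e-8, atol = 1e-12,
                                 method = "lsode", clamp_tol = 1e-9) {
  if (!is.numeric(init) || length(init) != 2L) {
    verr("init must be a numeric vector c(x, y)")
  }
  init <- unname(init)
  check_state(init[1], init[2])
  if (!is.finite(horizon) || horizon <= 0) verr("horizon must be > 0")
  br <- replicator_brackets(params)
  rhs <- function(t, s, parms) {
    x <- s[1L]; y <- s[2L]
    list(c(x * (1 - x) * br$manufacturer(y),
           y * (1 - y) * br$government(x)))
  }
  times <- seq(0, horizon, length.out = max(2L, as.integer(n_out)))
  # robustness ladder: the default multistep solver occasionally stalls
  # on near-corner passages of closed orbits or overshoots the boundary
  # by more than the clamp; fall through to lsoda, then the implicit
  # Runge-Kutta radau, and accept the first in-square solution
  df <- NULL
  last_problem <- "no solver attempted"
  for (m in unique(c(method, "lsoda", "radau"))) {
    sol <- try(suppressWarnings(
      deSolve::ode(y = c(x = init[1], y = init[2]), times = times,
                   func = rhs, parms = NULL, method = m,
                   rtol = rtol, atol = atol)), silent = TRUE)
    if (inherits(sol, "try-error") || nrow(sol) < length(times) ||
        anyNA(sol)) {
      last_problem <- sprintf("%s did not reach the horizon", m)
      next
    }
    cand <- as.data.frame(unclass(sol))
    names(cand) <- c("t", "x", "y")
    exc <- max(0, -min(cand$x), -min(cand$y),
               max(cand$x) - 1, max(cand$y) - 1)
    if (exc > clamp_tol) {
      last_problem <- sprintf(
        "%s left the unit square by %.3g (> clamp_tol %.3g)", m, exc,
        clamp_tol)
      next
    }
    df <- cand
    break
  }
  if (is.null(df)) {
    ierr(paste0("trajectory integration failed: ", last_problem))
  }
  df$x <- pmin(1, pmax(0, df$x))
  df$y <- pmin(1, pmax(0, df$y))
  attr(df, "params") <- params
  class(df) <- c("game_trajectory", "data.frame")
  df
}

#' @export
print.game_trajectory <- function(x, ...) {
  cat(sprintf(
    "replicator trajectory: %d points on [0, %.6g], start (%.4g, %.4g), end (%.4g, %.4g)\n",
    nrow(x), max(x$t), x$x[1], x$y[1], x$x[nrow(x)], x$y[nrow(x)]))
  invisible(x)
}

#' Write a trajectory as CSV
#'
#' Plain `t,x,y` CSV, one row per output time, floats at 10 significant
#' digits for reproducible diffs.
#'
#' @param traj a `game_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  lines <- c("t,x,y",
             sprintf("%.10g,%.10g,%.10g", traj$t, traj$x, traj$y))
  writeLines(lines, path)
  invisible(path)
}

#' Classify the long-run behaviour of a trajectory
#'
#' Inspects the tail of an integrated trajectory and assigns one of:
#' `vertex(a,b)` (settled within `tol` of a corner over the whole settle
#' window), `interior-fixed` (tail collapsed to an interior point where
#' the vector field nearly vanishes), `cycling` (persistent bounded
#' oscillation with no amplitude decay, the closed-orbit regime around an
#' interior centre), or `undetermined`.
#'
#' @param traj a `game_trajectory` (params travel in its attribute).
#' @param tol state-space convergence tolerance for the vertex and
#'   interior labels (default 1e-3, the resolution at which phase
#'   portraits are read).
#' @param settle_frac fraction of the horizon used as the settle window
#'   (default 0.1, i.e. the final 10 percent).
#' @return Object of class `long_run_outcome`: list with `label`,
#'   `terminal_state`, and a `diagnostics` list (corner distances, window
#'   diameter, amplitudes of the leading and trailing halves, terminal
#'   vector-field norm).
#' @export
detect_long_run_behavior <- function(traj, tol = 1e-3, settle_frac = 0.1) {
  df <- traj
  n <- nrow(df)
  horizon <- max(df$t)
  win <- df[df$t >= (1 - settle_frac) * horizon, , drop = FALSE]
  if (n < 20L || nrow(win) < 5L) {
    verr("trajectory too short to classify long-run behaviour")
  }
  params <- attr(traj, "params")
  terminal <- c(x = df$x[n], y = df$y[n])

  corners <- list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  corner_dist <- vapply(corners, function(cc) {
    max(sqrt((win$x - cc[1])^2 + (win$y - cc[2])^2))
  }, numeric(1))
  names(corner_dist) <- vapply(corners, function(cc) {
    sprintf("(%d,%d)", cc[1], cc[2])
  }, character(1))

  diam <- sqrt(diff(range(win$x))^2 + diff(range(win$y))^2)
  field_norm <- sqrt(sum(vector_field(params, terminal[1], terminal[2])^2))
  half1 <- df[df$t <= horizon / 2, , drop = FALSE]
  half2 <- df[df$t > horizon / 2, , drop = FALSE]
  amp <- function(d) sqrt(diff(range(d$x))^2 + diff(range(d$y))^2)
  amp1 <- amp(half1); amp2 <- amp(half2)

  diagnostics <- list(corner_distances = corner_dist,
                      window_diameter = diam,
                      terminal_field_norm = field_norm,
                      amplitude_first_half = amp1,
                      amplitude_second_half = amp2)

  # the interior label demands proximity to the actual mixed rest point,
  # not merely a small vector field (which slow corner approaches share)
  interior_pt <- {
    eqs <- find_equilibria(params)
    pts <- Filter(function(r) r$kind == "interior", eqs)
    if (length(pts)) pts[[1]]$point else NULL
  }
  interior_dist <- if (is.null(interior_pt)) Inf else
    sqrt(sum((terminal - interior_pt)^2))
  diagnostics$interior_distance <- interior_dist

  label <- "undetermined"
  hit <- which(corner_dist < tol)
  if (length(hit)) {
    label <- paste0("vertex", names(corner_dist)[hit[1]])
  } else if (diam < tol && field_norm < tol && interior_dist < tol) {
    label <- "interior-fixed"
  } else if (amp2 > 10 * tol && amp2 > 0.5 * amp1 && amp2 < 2 * amp1) {
    # persistent, non-decaying bounded oscillation: closed-orbit regime
    label <- "cycling"
  }

  out <- list(label = label, terminal_state = terminal,
              diagnostics = diagnostics)
  class(out) <- "long_run_outcome"
  out
}

#' @export
print.long_run_outcome <- function(x, ...) {
  cat(sprintf("long-run outcome: %s, terminal state (%.6g, %.6g)\n",
              x$label, x$terminal_state[1], x$terminal_state[2]))
  invisible(x)
}

#' Integrate until the long-run outcome is determined
#'
#' Convenience wrapper: integrates from `init` over `horizon`, classifies
#' the outcome, and — if it is still `undetermined` (slow convergence or
#' an orbit period comparable to the horizon) — re-integrates with a
#' doubled horizon, up to `max_horizon`.
#'
#' @inheritParams integrate_trajectory
#' @param max_horizon horizon cap for the doubling schedule.
#' @param tol vertex tolerance passed to [detect_long_run_behavior()].
#' @return A `long_run_outcome`.
#' @export
simulate_long_run <- function(params, init, horizon = 500,
                              max_horizon = 16000, tol = 1e-3,
                              n_out = 2001) {
  h <- horizon
  repeat {
    tr <- integrate_trajectory(params, init, horizon = h, n_out = n_out)
    oc <- detect_long_run_behavior(tr, tol = tol)
    if (oc$label != "undetermined" || h >= max_horizon) return(oc)
    h <- h * 2
  }
}
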
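# Phase portraits, parameter sweeps, the critical fine, parameter sampling.

test_that("baseline phase portrait sends every interior start to (0, 1)", {
  pp <- run_baseline(base_p(), starts = as.matrix(expand.grid(
    x = c(0.2, 0.5, 0.8), y = c(0.2, 0.5, 0.8))))
  labels <- vapply(pp$outcomes, `[[`, character(1), "label")
  expect_true(all(labels == "vertex(0,1)"))
  expect_identical(unname(pp$tally[["vertex(0,1)"]]), 9L)
})

test_that("centre-regime portrait cycles from every interior start", {
  pp <- run_baseline(center_p(), starts = rbind(c(0.4, 0.5), c(0.6, 0.7)),
                     horizon = 1000)
  labels <- vapply(pp$outcomes, `[[`, character(1), "label")
  expect_true(all(labels == "cycling"))
})

test_that("the critical fine sits at 4.5 under the baseline calibration", {
  th <- find_critical_fine(base_p(), bracket = c(0, 20), tol = 1e-6)
  expect_equal(th$critical_value, 4.5, tolerance = 1e-6)
  expect_equal(th$closed_form, 4.5)
  expect_equal(th$critical_value, th$closed_form, tolerance = 1e-6)
})

test_that("no-crossing brackets are rejected", {
  flat <- game_params(RV1 = 6, RV2 = 6, validate = FALSE)  # epsilon == 0
  expect_error(find_critical_fine(flat), "no crossing",
               class = "vaxgame_validation_error")
  expect_error(find_critical_fine(base_p(), bracket = c(5, 20)),
               "no crossing", class = "vaxgame_validation_error")
})

test_that("bisection matches the closed-form critical fine on random sets", {
  ps <- sample_parameters(seed = 19, n = 50)
  tested <- 0L
  for (p in ps) {
    bl <- p$beta * p$lambda
    closed <- (p$RV2 - p$RV1) / bl - p$RV2 - p$FV2
    if (closed <= 0) next  # temptation below the passive channel already
    th <- find_critical_fine(p, bracket = c(0, 2 * closed + 10), tol = 1e-7)
    expect_equal(th$critical_value, closed, tolerance = 1e-5)
    tested <- tested + 1L
  }
  expect_gte(tested, 20L)
})

test_that("an FV1 sweep walks through deterrence regimes in order", {
  sw <- sweep_parameter(base_p(), "FV1", c(3, 4, 5, 6, 8, 10))
  tb <- sw$table
  expect_true(all(tb$valid))
  expect_identical(tb$case_id,
                   c("outside_enumerated", "outside_enumerated",
                     "cycle_case", "case3_11", "case3_11", "case3_11"))
  # FV1 = 5 has the cycle ordering but its interior point falls outside
  # the square at these cost/benefit levels, so the corner signs still
  # send trajectories to (0, 1); true closed orbits need the centre inside
  expect_identical(tb$outcome,
                   c("vertex(0,1)", "vertex(0,1)", "vertex(0,1)",
                     "vertex(1,1)", "vertex(1,1)", "vertex(1,1)"))
  expect_true(all(diff(tb$epsilon) < 0))
})

test_that("sweep regime boundaries match the closed-form crossings", {
  p <- base_p()
  bl <- p$beta * p$lambda
  fv1_bl <- (p$RV2 - p$RV1) / bl - p$RV2 - p$FV2        # epsilon = beta*lambda
  fv1_a <- (p$RV2 - p$RV1) / p$alpha - p$RV2 - p$FV2    # epsilon = alpha
  expect_equal(fv1_bl, 4.5)
  expect_equal(fv1_a, 16 / 3)
  grid <- seq(3, 7, by = 0.4)  # grid points avoid the exact crossings
  for (v in grid) {
    cid <- classify_regime(update_params(p, FV1 = v))$case_id
    want <- if (v < fv1_bl) "outside_enumerated"
            else if (v < fv1_a) "cycle_case"
            else "case3_11"
    expect_identical(cid, want)
  }
})

test_that("a lambda sweep flips the ordering of beta*lambda against epsilon", {
  sw <- sweep_parameter(base_p(), "lambda", c(0.1, 0.4, 0.7))
  tb <- sw$table
  expect_false(tb$case_id[1] == "cycle_case")  # beta*lambda = 0.08 << eps
  expect_identical(tb$case_id[3], "cycle_case")  # 0.3 < 1/3 < 0.56
})

test_that("sweeps tolerate invalid substitutions without aborting", {
  sw <- sweep_parameter(base_p(), "alpha", c(0.2, 0.5, 0.9))
  tb <- sw$table
  expect_identical(tb$valid, c(TRUE, TRUE, FALSE))  # alpha = 0.9 > beta
  expect_true(is.na(tb$outcome[3]))
  expect_error(sweep_parameter(base_p(), "FV3", 1:3),
               class = "vaxgame_validation_error")
})

test_that("the parameter sampler is deterministic and honours constraints", {
  a <- sample_parameters(seed = 1, n = 10)
  b <- sample_parameters(seed = 1, n = 10)
  expect_identical(a, b)
  for (p in a) expect_true(validate_params(p)$valid)
  for (p in sample_parameters(seed = 2, n = 10, case = "cycle_case")) {
    dq <- derived_quantities(p)
    expect_true((p$alpha < dq$epsilon && dq$epsilon < dq$beta_lambda) ||
                  (p$alpha > dq$epsilon && dq$epsilon > dq$beta_lambda))
    expect_length(find_equilibria(p), 5)  # centre inside the square
  }
  for (p in sample_parameters(seed = 3, n = 10, require_mu_gt_1 = TRUE)) {
    expect_gt(p$FV1, p$RV2)
  }
})
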
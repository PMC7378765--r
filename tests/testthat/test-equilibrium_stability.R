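# Equilibrium enumeration, Jacobian stability, regime classification.

corner_set <- function(eqs) {
  pure <- Filter(function(r) r$kind == "pure", eqs)
  sort(vapply(pure, function(r) sprintf("(%g,%g)", r$point[1], r$point[2]),
              character(1)))
}

test_that("baseline admits the four corners and no interior rest point", {
  eqs <- find_equilibria(base_p())
  expect_length(eqs, 4)
  expect_identical(corner_set(eqs), c("(0,0)", "(0,1)", "(1,0)", "(1,1)"))
  # the interior candidate exists algebraically but far outside (0,1)
  cand <- attr(eqs, "interior_candidate")
  expect_equal(cand[["x"]], 1 - (2 - 1) / ((0.32 - 0.3) * 3),
               tolerance = 1e-12)
  expect_lt(cand[["x"]], 0)
  expect_false(attr(eqs, "degenerate"))
})

test_that("the centre-regime calibration adds the interior point (0.5, 8/13)", {
  eqs <- find_equilibria(center_p())
  expect_length(eqs, 5)
  interior <- eqs[[5]]
  expect_identical(interior$kind, "interior")
  expect_state_equal(interior$point, c(0.5, 8 / 13))
})

test_that("equal channel detection probabilities degenerate the interior point", {
  p <- update_params(base_p(), lambda = 0.375)  # beta*lambda == alpha
  eqs <- find_equilibria(p)
  expect_length(eqs, 4)
  expect_true(attr(eqs, "degenerate"))
})

test_that("corner Jacobians have zero off-diagonals and the expected entries", {
  p <- base_p()
  J00 <- jacobian_entries(p, 0, 0)
  expect_equal(J00$a11, -0.16)
  expect_equal(J00$a22, 0.94)
  expect_identical(abs(J00$a12), 0)
  expect_identical(abs(J00$a21), 0)
  J01 <- jacobian_entries(p, 0, 1)
  expect_equal(J01$a11, -0.4)
  expect_equal(J01$a22, -0.94)
  # off-diagonals vanish at every corner for random parameter sets
  for (q in sample_parameters(seed = 3, n = 20)) {
    for (cc in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))) {
      J <- jacobian_entries(q, cc[1], cc[2])
      expect_identical(abs(J$a12) + abs(J$a21), 0)
    }
  }
})

test_that("stability labels follow the trace/determinant conditions", {
  eqs <- equilibrium_analysis(base_p())
  labels <- vapply(eqs, `[[`, character(1), "label")
  pts <- vapply(eqs, function(r) sprintf("(%g,%g)", r$point[1], r$point[2]),
                character(1))
  expect_identical(labels[pts == "(0,1)"], "ESS")
  expect_identical(labels[pts == "(0,0)"], "saddle")
  expect_identical(labels[pts == "(1,0)"], "unstable")
  expect_identical(sum(labels == "ESS"), 1L)
})

test_that("the interior rest point has zero trace and is a centre", {
  eqs <- equilibrium_analysis(center_p())
  interior <- Filter(function(r) r$kind == "interior", eqs)[[1]]
  expect_lt(abs(interior$jacobian$trace), 1e-10)
  expect_gt(interior$jacobian$det, 0)
  expect_identical(interior$label, "center")
  # zero trace holds across every sampled set admitting an interior point
  for (p in sample_parameters(seed = 5, n = 40)) {
    eqs <- find_equilibria(p)
    if (length(eqs) == 5) {
      J <- jacobian_entries(p, eqs[[5]]$point[1], eqs[[5]]$point[2])
      expect_lt(abs(J$trace), 1e-10)
    }
  }
})

test_that("interior y* equals (beta*lambda - epsilon)/(beta*lambda - alpha)", {
  for (p in sample_parameters(seed = 9, n = 50)) {
    dq <- derived_quantities(p)
    denom <- dq$beta_lambda - p$alpha
    if (abs(denom) < 1e-9) next
    cand <- attr(find_equilibria(p), "interior_candidate")
    expect_equal(cand[["y"]], (dq$beta_lambda - dq$epsilon) / denom,
                 tolerance = 1e-10)
  }
})

test_that("regime classification covers the enumerated cases and the baseline gap", {
  reg <- classify_regime(base_p())
  expect_identical(reg$case_id, "outside_enumerated")
  expect_identical(reg$ordering, "epsilon > beta*lambda > alpha")
  expect_identical(reg$cost_comparison, 1)
  expect_length(reg$sign_analysis_ess, 1)
  expect_state_equal(reg$sign_analysis_ess[[1]], c(0, 1))

  reg10 <- classify_regime(update_params(base_p(), FV1 = 10))
  expect_identical(reg10$case_id, "case3_11")
  expect_state_equal(reg10$predicted_ess, c(1, 1))
  expect_true(reg10$agreement)

  reg5 <- classify_regime(update_params(base_p(), FV1 = 5))
  expect_identical(reg5$case_id, "cycle_case")
  expect_null(reg5$predicted_ess)

  # exact tie on a decisive quantity is flagged, never silently cased
  regc <- classify_regime(update_params(base_p(), FV1 = 4.5))
  expect_identical(regc$case_id, "critical")
})

test_that("regime predictions agree with simulated long-run outcomes", {
  vertex_label <- function(pt) sprintf("vertex(%g,%g)", pt[1], pt[2])
  set.seed(21)
  for (case in c("case2_00", "case3_11")) {
    for (p in sample_parameters(seed = 13, n = 4, case = case)) {
      reg <- classify_regime(p)
      starts <- random_states(3)
      for (i in seq_len(nrow(starts))) {
        oc <- simulate_long_run(p, starts[i, ])
        expect_identical(oc$label, vertex_label(reg$predicted_ess))
      }
    }
  }
  for (p in sample_parameters(seed = 17, n = 3, case = "cycle_case")) {
    oc <- simulate_long_run(p, c(0.4, 0.6))
    expect_identical(oc$label, "cycling")
  }
})

test_that("the claimed baseline rest point (0,0) conflicts with the sign analysis", {
  chk <- check_claimed_ess(base_p(), claim = c(0, 0))
  expect_true(chk$conflict)
  expect_identical(chk$claim_label, "saddle")
  expect_state_equal(chk$sign_analysis_ess[[1]], c(0, 1))
  # and the corner the signs certify is confirmed when claimed
  chk01 <- check_claimed_ess(base_p(), claim = c(0, 1))
  expect_false(chk01$conflict)
})
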
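# Shared fixtures: the baseline calibration and a variant whose interior
# rest point is a centre (closed-orbit regime).

base_p <- function() baseline_params()

# Raising CG1 and RG and setting FV1 = 5 moves the profit-loss ratio
# strictly between the two detection probabilities and puts the interior
# rest point at (0.5, 8/13): the centre / closed-orbit regime.
center_p <- function() update_params(baseline_params(),
                                     CG1 = 1.9, RG = 10, FV1 = 5)

# Random interior states away from the edges, reproducibly.
random_states <- function(n, margin = 0.05) {
  cbind(x = stats::runif(n, margin, 1 - margin),
        y = stats::runif(n, margin, 1 - margin))
}

expect_state_equal <- function(got, want, tol = 1e-10) {
  expect_equal(unname(got), unname(want), tolerance = tol)
}
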
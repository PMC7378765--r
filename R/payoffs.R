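# Bimatrix payoffs and expected (fitness) payoffs of the two populations.

#' Build the 2x2 bimatrix of stage-game payoffs
#'
#' Rows index the manufacturer's strategy (self-discipline /
#' non-self-discipline), columns the regulator's (active / passive
#' supervision).  Each cell holds the pair (manufacturer payoff,
#' government payoff).  Under passive supervision nothing happens unless a
#' third party reports (probability `lambda`); a reported self-disciplined
#' firm still bears the inspection-cooperation cost `CV`, while a reported
#' non-self-disciplined firm is caught with probability `beta` and then
#' pays the fine `FV1` and rectification cost `FV2` and forfeits the
#' illicit revenue.  Supervision costs enter as the effective costs
#' `CG1/pi` and `CG2/psi`.
#'
#' @param params a `game_params` object.
#' @return Object of class `payoff_matrix`: list of two 2x2 numeric
#'   matrices `manufacturer` and `government`, with dimnames
#'   `c("self_discipline", "non_self_discipline")` by
#'   `c("active", "passive")`.
#' @examples
#' pm <- payoff_matrix(baseline_params())
#' pm$manufacturer["self_discipline", "active"]  # RV1 - CV = 1
#' @export
payoff_matrix <- function(params) {
  p <- params
  ec <- effective_costs(p)
  cA <- ec[["active"]]; cP <- ec[["passive"]]
  loss <- p$FV1 + p$FV2

  m_sd_act <- p$RV1 - p$CV
  m_sd_pas <- p$lambda * (p$RV1 - p$CV) + (1 - p$lambda) * p$RV1
  m_ns_act <- (1 - p$alpha) * p$RV2 - p$alpha * loss - p$CV
  m_ns_pas <- p$lambda * ((1 - p$beta) * p$RV2 - p$beta * loss - p$CV) +
    (1 - p$lambda) * p$RV2

  g_sd_act <- -cA
  g_sd_pas <- p$lambda * (-cP)
  g_ns_act <- p$alpha * p$RG - cA
  g_ns_pas <- p$lambda * (p$beta * (p$RG - cP) + (1 - p$beta) * (-cP))

  dn <- list(c("self_discipline", "non_self_discipline"),
             c("active", "passive"))
  out <- list(
    manufacturer = matrix(c(m_sd_act, m_ns_act, m_sd_pas, m_ns_pas),
                          2, 2, dimnames = dn),
    government = matrix(c(g_sd_act, g_ns_act, g_sd_pas, g_ns_pas),
                        2, 2, dimnames = dn))
  class(out) <- "payoff_matrix"
  out
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat("payoff bimatrix (manufacturer, government):\n")
  for (i in 1:2) for (j in 1:2) {
    cat(sprintf("  (%s, %s): (%.6g, %.6g)\n",
                rownames(x$manufacturer)[i], colnames(x$manufacturer)[j],
                x$manufacturer[i, j], x$government[i, j]))
  }
  invisible(x)
}

check_state <- function(x, y) {
  if (!is.finite(x) || !is.finite(y) || x < 0 || x > 1 || y < 0 || y > 1) {
    verr(sprintf("state (%.6g, %.6g) outside the unit square", x, y))
  }
}

#' Expected payoffs at a population state
#'
#' Given shares `x` (self-disciplined manufacturers) and `y` (actively
#' supervising regulators), returns each pure strategy's expected payoff
#' against the opposing population, and the population averages.
#' `E11`/`E12` (manufacturer: self / non-self-discipline) depend on `y`
#' only; `E21`/`E22` (government: active / passive) depend on `x` only;
#' `E1bar = x E11 + (1 - x) E12`, `E2bar = y E21 + (1 - y) E22`.
#'
#' @param params a `game_params` object.
#' @param x share of self-disciplined manufacturers, in \[0, 1\].
#' @param y share of actively supervising regulators, in \[0, 1\].
#' @return Named list with `E11`, `E12`, `E1bar`, `E21`, `E22`, `E2bar`.
#' @export
expected_payoffs <- function(params, x, y) {
  check_state(x, y)
  pm <- payoff_matrix(params)
  M <- pm$manufacturer; G <- pm$government
  E11 <- y * M[1, 1] + (1 - y) * M[1, 2]
  E12 <- y * M[2, 1] + (1 - y) * M[2, 2]
  E21 <- x * G[1, 1] + (1 - x) * G[2, 1]
  E22 <- x * G[1, 2] + (1 - x) * G[2, 2]
  list(E11 = E11, E12 = E12, E1bar = x * E11 + (1 - x) * E12,
       E21 = E21, E22 = E22, E2bar = y * E21 + (1 - y) * E22)
}
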
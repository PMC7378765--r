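---
title: "Replicator dynamics of vaccine-market regulation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicator dynamics of vaccine-market regulation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxgame)
```

## The model

Two boundedly rational populations interact repeatedly: vaccine
manufacturers choose between **self-discipline** (producing qualified
vaccines, revenue $R_{V1}$) and **non-self-discipline** (revenue
$R_{V2} > R_{V1}$, but a fine-plus-reputation loss $F_{V1}$ and a
rectification cost $F_{V2}$ if caught), and a government regulator
chooses between **active supervision** (proactive inspection, success
probability $\alpha$, effective cost $C_{G1}/\pi$) and **passive
supervision** (inspection only after a third-party report, which arrives
with probability $\lambda$; success probability $\beta > \alpha$,
effective cost $C_{G2}/\psi$). Uncovering a non-self-disciplined firm is
worth $R_G$ to the regulator; a firm bears a cooperation cost $C_V$
whenever it is actually inspected. Bribery between the two sides is
assumed away, and all payoffs are in dimensionless "payoff units" — no
currency calibration is attempted.

The state is $(x, y) \in [0,1]^2$: the share of self-disciplined
manufacturers and of actively supervising regulators. With $E_{11},
E_{12}$ the expected payoffs of the two manufacturer strategies (they
depend on $y$ only) and $E_{21}, E_{22}$ those of the regulator (they
depend on $x$ only), the replicator dynamics are

$$\dot x = x(1-x)\,(E_{11} - E_{12}), \qquad
  \dot y = y(1-y)\,(E_{21} - E_{22}),$$

with the closed-form brackets

$$E_{11} - E_{12} = y\,S\,(\alpha - \beta\lambda) + R_{V1} - R_{V2}
  + \beta\lambda S, \qquad S = R_{V2} + F_{V1} + F_{V2},$$
$$E_{21} - E_{22} = (\alpha - \beta\lambda)R_G(1 - x)
  + \lambda C_{G2}/\psi - C_{G1}/\pi.$$

`vector_field()` implements the brackets; `expected_payoffs()` rebuilds
the same differences from the bimatrix cells, and the test suite holds
the two routes together at $10^{-10}$ on hundreds of random parameter
sets.

### A note on the cost coefficients

The strictness coefficient $\pi$ and the public-awareness coefficient
$\psi$ *reduce* the supervision costs: the effective costs are the
quotients $C_{G1}/\pi$ and $C_{G2}/\psi$. This is the only reading under
which the government bracket and the interior-equilibrium coordinate
$x^*$ are mutually consistent, and it leaves every baseline number
unchanged (the baseline has $\pi = \psi = 1$). The validity constraint is
$C_{G2}/\psi > C_{G1}/\pi > 0$: reacting to a report is dearer per case
than routine inspection.

### The penalty coefficient is a warning, not an error

The model argues that supervision only has teeth when
$\mu = F_{V1}/R_{V2} > 1$. The baseline calibration itself has
$\mu = 4/6 < 1$, so `validate_params()` reports $\mu \le 1$ as a warning
while treating the structural constraints ($0 < \alpha < \beta \le 1$,
$R_{V2} > R_{V1}$, the cost ordering) as hard errors. Reproducing the
baseline experiments requires tolerating the weak-penalty regime.

## Equilibria and stability

The four corners of the square are rest points for every parameter set.
An interior rest point

$$x^* = 1 - \frac{\lambda C_{G2}/\psi - C_{G1}/\pi}
                 {(\beta\lambda - \alpha) R_G}, \qquad
  y^* = \frac{R_{V1} - R_{V2} + \beta\lambda S}{S(\beta\lambda - \alpha)}
      = \frac{\beta\lambda - \varepsilon}{\beta\lambda - \alpha}$$

exists when both coordinates fall strictly inside $(0,1)$; here
$\varepsilon = (R_{V2} - R_{V1})/S$ is the **profit-loss ratio** of
non-self-discipline — the temptation relative to the downside.
`classify_equilibrium()` applies the standard planar conditions: an
equilibrium is an ESS iff $\operatorname{tr} J < 0$ and $\det J > 0$, a
saddle iff $\det J < 0$, and the interior point — where both diagonal
entries vanish, so the trace is exactly zero while
$\det J = x^*(1-x^*)y^*(1-y^*)\,S\,R_G\,(\beta\lambda-\alpha)^2 > 0$ —
is a centre: closed orbits, stable but not asymptotically stable.

Decisive quantities within $10^{-9}$ of zero are reported as
`non-hyperbolic` (corners) or make the regime `critical` rather than
being silently assigned; the strict inequality chains themselves are
evaluated in exact floating-point arithmetic with no padding.

## Regimes

The ordering of $\varepsilon$ against the two channel detection
probabilities $\alpha$ and $\beta\lambda$, together with the sign of
$\lambda C_{G2}/\psi - C_{G1}/\pi$, selects the regime
(`classify_regime()`): the enumerated corner-ESS cases, and the
transition regime ($\varepsilon$ strictly between $\alpha$ and
$\beta\lambda$) where no ESS exists and interior trajectories are closed
orbits around the centre.

Two deliberate transparencies:

* **The ordering alone does not imply cycling.** It guarantees
  $y^* \in (0,1)$ but not $x^* \in (0,1)$; e.g. the baseline with
  $\alpha = 0.5$ has the transition ordering yet $(1,1)$ is an ESS
  because the centre falls outside the square. `classify_regime()`
  keeps the literal conditions; the sampler's `case = "cycle_case"`
  targeting additionally requires the interior rest point, which is the
  regime the closed-orbit phase portrait actually depicts.
* **The baseline falls outside every enumerated case** (its ordering
  $\varepsilon > \beta\lambda > \alpha$ pairs with
  $\lambda C_{G2}/\psi > C_{G1}/\pi$). The classifier therefore always
  also runs direct corner sign analysis and reports both. At the
  baseline that analysis certifies $(0,1)$ — firms defect, the
  regulator stays active — as the unique ESS, with $(0,0)$ a saddle
  ($a_{11} = -0.16 < 0$, $a_{22} = +0.94 > 0$). A published simulation
  narrative for this calibration claims convergence to $(0,0)$ instead;
  `check_claimed_ess()` exposes exactly this conflict rather than
  adjusting parameters to hide it, and long integration confirms
  $(0,1)$.

## Numerical choices

* **Integration**: `deSolve` with `lsode` at `rtol = 1e-8`,
  `atol = 1e-12`, with an automatic fallback to `lsoda` and then the
  implicit Runge–Kutta `radau` when a solver stalls on a near-corner
  passage or overshoots the boundary. The square is forward-invariant
  for the exact flow; numerical excursions below $10^{-9}$ are projected
  back, larger ones are an integration error (after the full ladder
  fails). These tolerances keep closed orbits from artificially
  spiralling over the test horizons.
* **Long-run detection** (`detect_long_run_behavior()`): a trajectory is
  a `vertex` outcome if its final 10 % stays within $10^{-3}$ of a
  corner (the resolution at which one reads a phase portrait);
  `interior-fixed` requires both a collapsed tail *and* proximity to the
  actual mixed rest point (a small vector field alone is shared by slow
  corner approaches); `cycling` requires persistent bounded oscillation
  with no amplitude decay between the two halves of the horizon.
  `simulate_long_run()` doubles the horizon (default 500, cap 16 000)
  until the label resolves, which covers slowly converging sets and
  orbits with long periods.
* **Threshold finding** (`find_critical_fine()`): plain bisection on the
  sign of $\varepsilon(F_{V1}) - \beta\lambda$ to a bracket width of
  $10^{-6}$, cross-checked against the closed form
  $F_{V1}^* = (R_{V2}-R_{V1})/(\beta\lambda) - R_{V2} - F_{V2}$, which
  is 4.5 at the baseline. The analytic criterion reproduces what a
  simulated cooperation-probability scan locates, without the noise of
  reading it off trajectories. The second crossing,
  $\varepsilon = \alpha$ at $(R_{V2}-R_{V1})/\alpha - R_{V2} - F_{V2}
  = 16/3$, bounds the transition band from above.
* **Sweeps** default to 6–10 grid points spanning the regime boundaries
  from the common start $(0.5, 0.5)$ — the uninformative midpoint.

## What the parameter sampler emulates — and what it does not

`sample_parameters()` draws baseline-scale sets (costs of order 1–8,
revenues 1–12, probabilities away from the degenerate edges) satisfying
every hard constraint, optionally $\mu > 1$ or a requested regime, by
rejection. It emulates the *structural* variety of the model's parameter
space, not empirical vaccine-market data: passing property tests shows
the mathematics (bracket identities, zero trace, forward invariance,
prediction–simulation agreement) holds across that space, not that any
particular real market sits in a particular regime. Test problem sizes
are 200 sets for the bracket oracle, 100 integrations for forward
invariance, 50 sets each for the threshold cross-check and the
regime-agreement property.

## Known limitations

* Deterministic infinite-population replicator dynamics only — no
  finite-population (Moran/Fermi) noise, no more than two strategies or
  players.
* The centre case is certified by linearisation plus bounded-band
  checks over finite horizons; no Lyapunov function or first integral
  is constructed.
* Basins are explored by sampling starts, not computed globally.
* Sweep directions for $\alpha$, $\beta$, $\lambda$, $\pi$, $\psi$ are
  qualitative; only the $F_{V1}$ boundaries have closed-form targets.
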
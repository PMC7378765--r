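# vaxgame

Evolutionary game dynamics of vaccine-manufacturer self-discipline under
government regulation.

Defective-vaccine scandals are a regulator's problem long before they are
a court's: a manufacturer weighs the excess revenue of cutting corners
against the fine, rectification cost and reputation loss it faces *if
caught*, while the regulator weighs proactive inspection against waiting
for third-party reports. `vaxgame` implements this interaction as an
asymmetric two-population evolutionary game and provides the analysis a
policy modeller needs: payoffs, replicator dynamics, equilibrium and
stability classification, regime analysis, parameter sweeps and a
critical-fine threshold finder.

## The model in brief

State `(x, y) ∈ [0,1]²`: the share of self-disciplined manufacturers and
of actively supervising regulators. Replicator dynamics

```
dx/dt = x(1−x)[ yS(α−βλ) + RV1 − RV2 + βλS ],   S = RV2 + FV1 + FV2
dy/dt = y(1−y)[ (α−βλ)RG(1−x) + λCG2/ψ − CG1/π ]
```

where `α`/`β` are the success probabilities of active/passive
supervision, `λ` the third-party reporting probability, `RV1 < RV2` the
honest/illicit revenues, `FV1` the fine plus reputation loss, `FV2` the
rectification cost, `RG` the regulator's benefit from an uncovered
violation, and `CG1/π`, `CG2/ψ` the effective supervision costs. The
profit–loss ratio

```
ε = (RV2 − RV1) / (RV2 + FV1 + FV2)
```

is the temptation of non-self-discipline relative to its downside; the
ordering of `ε` against `α` and `βλ` (plus a cost comparison) selects the
dynamic regime — corner ESSs, or closed orbits around an interior centre
with exactly zero Jacobian trace. See the methods vignette
(`vignettes/vaxgame-methods.Rmd`) for the full account.

## Worked example

```r
library(vaxgame)
p <- baseline_params()   # CG1=1, CG2=5, RG=3, α=0.3, β=0.8, λ=0.4,
                         # RV1=2, RV2=6, FV1=4, FV2=2, CV=1, π=ψ=1

classify_regime(p)
#> regime: outside_enumerated (epsilon > beta*lambda > alpha; lambda*CG2/psi > CG1/pi)
#>   sign-analysis ESS: (0, 1)

find_critical_fine(p)
#> critical FV1 = 4.5000002 (bisection, 25 iters; closed form 4.5)

simulate_long_run(p, c(0.5, 0.5))
#> long-run outcome: vertex(0,1), terminal state (4.61752e-84, 1)

check_claimed_ess(p, c(0, 0))$message
#> claimed stable point (0, 0) is a saddle under the Jacobian sign
#> conditions; certified stable corner(s): (0, 1)
```

Reading the output: under the baseline calibration the temptation
`ε = 1/3` exceeds both detection probabilities, so manufacturers drift to
non-self-discipline (`x → 0`) while active supervision remains the
regulator's best response (`y → 1`). Raising the fine past the critical
value `FV1* = 4.5` pushes `ε` below `βλ = 0.32` (and past `FV1 = 16/3`
below `α = 0.3`), after which self-discipline with active supervision,
`(1,1)`, becomes the ESS:

```r
sweep_parameter(p, "FV1", c(3, 4, 5, 6, 8, 10))
#>  value case_id            outcome      ...
#>      3 outside_enumerated vertex(0,1)
#>      4 outside_enumerated vertex(0,1)
#>      5 cycle_case         vertex(0,1)
#>      6 case3_11           vertex(1,1)
#>      8 case3_11           vertex(1,1)
#>     10 case3_11           vertex(1,1)
```

The last line of the stability story: any calibration admitting an
interior mixed equilibrium (e.g. `update_params(p, CG1 = 1.9, RG = 10,
FV1 = 5)`, interior point `(0.5, 8/13)`) has exactly zero Jacobian trace
there — a centre, around which strategies cycle forever instead of
settling.

## Command line

A thin wrapper over the same functions ships at `inst/cli/vaxgame`
(installed under `system.file("cli", "vaxgame", package = "vaxgame")`):

```sh
Rscript inst/cli/vaxgame threshold                       # JSON, critical_value 4.5
Rscript inst/cli/vaxgame equilibria --FV1 10             # equilibrium reports
Rscript inst/cli/vaxgame simulate --x0 0.5 --y0 0.5 --out traj.csv
Rscript inst/cli/vaxgame sweep --param FV1 --values 3,4,5,6,8,10 --out-dir out/
```

Parameters come from `--<name>` flags or a flat `name = value` config
file (`--config`); results are CSV/JSON at 10 significant digits, logs go
to standard error.

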
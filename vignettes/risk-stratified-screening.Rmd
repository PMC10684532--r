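---
title: "Choosing risk-group thresholds for screening intervals: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing risk-group thresholds for screening intervals: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenopt)
```

# The problem

A short-horizon risk model (for instance an imaging AI that projects 3-year
breast-cancer risk from a screening mammogram) ranks the screening
population. A programme that screens everyone at the same interval can then
be re-designed: screen the high-risk tail more often, the low-risk bulk less
often, holding the total number of screens fixed. `screenopt` formalizes the
choice of *where to cut* the risk distribution and *which interval to attach
to each group* as an optimization over expected advanced-cancer incidence.
"Advanced" is whatever stage endpoint the stage-mix parameters encode; the
defaults use node-positive breast cancer, a strong surrogate for screening
benefit in trials.

# Natural-history model

The detection side is a two-state progression model. Preclinical,
screen-detectable disease becomes symptomatic at exponential rate
$\lambda$ per year; screens arrive every $u$ years with per-screen
sensitivity $D$; onset is uniform within a screening round. Conditional on a
cancer being diagnosed, the probability it is screen-detected is

$$ s(u) = \frac{D\,(1 - e^{-\lambda u})}{\lambda u\,\{1 - (1-D)e^{-\lambda u}\}}. $$

This closed form is usually presented as an approximation; under the exact
generative model just stated (uniform onset, exponential sojourn, geometric
per-screen detection) it is exact, which is what the package's event-level
Monte-Carlo test verifies: simulated detection fractions at $10^5$
replicates agree within three standard errors for intervals of 1–6 years.
That simulation is the validity evidence we rely on; no further validity
domain is imposed, any $\lambda u > 0$ is accepted.

Stage is mixed over detection mode: screen-detected cancers are advanced
with probability $a$, interval cancers with probability $b$, giving the
per-regimen adjustment factor $c_j = a\,s(u_j) + b\,(1 - s(u_j))$ and the
advanced-cancer risk $p_{kj} = r_k c_j$ for a stratum with invasive risk
$r_k$.

Parameter defaults, all overridable in `nh_params()`:

| parameter | default | units | rationale |
|---|---|---|---|
| `lambda_rate` ($\lambda$) | 0.25 | /year | sojourn-time estimates from randomized mammography trials |
| `sensitivity` ($D$) | 0.92 | probability | mammography sensitivity in the screened age range |
| `adv_frac_screen` ($a$) | 0.22 | probability | node-positive fraction among screen-detected cancers |
| `adv_frac_interval` ($b$) | 0.53 | probability | node-positive fraction among interval cancers |
| `horizon_years` | 6 | years | costing horizon over which screens are counted |

All four are held constant across risk quantiles by default. The
justification in the intended application is empirical — the AI score is
only weakly correlated with age and with breast density, the dominant
drivers of sojourn and sensitivity heterogeneity — but the API accepts a
pre-computed `p_matrix` in `build_problem()` for stratified extensions.
`D = 0` is accepted and returns $s = 0$ by continuity rather than erroring,
so sensitivity sweeps can touch the boundary.

A note on the default detection-mode table: `node_positive_table()` defaults
to intervals 1–5 years. The published five-row table this mirrors labels its
candidate set as 1, 2, 3, 4 and 6 years, but its fifth row (54%
screen-detected, 36% node-positive) is what the stated parameters give at a
**5-year** interval ($u = 6$ gives 49%/38%); we therefore treat the fifth
row as a 5-year interval. Percentages in this table are rounded half away
from zero, at the presentation layer only.

# The optimization

With $K$ equal-weight quantiles, regimens $j = 1,\dots,m$ with per-person
costs $h_j$ (screens per head over the horizon; `horizon / interval` by
default, so a 4-yearly regimen costs a non-integer 1.5), and budget $H$, the
population programme is the LP

$$ \min_X \sum_{kj} x_{kj} p_{kj} \quad \text{s.t.} \quad
   \sum_j x_{kj} = 1, \quad \sum_{kj} h_{kj} x_{kj} \le H, \quad
   0 \le x_{kj} \le 1 . $$

Costs may vary by quantile ($h_{kj}$, a $K \times m$ matrix) but default to
$h_j$; the triennial-equivalent budget at $K = 100$ is $H = 200$.

**Solver.** The LP has exactly one constraint coupling the rows, so it is a
continuous knapsack: for a multiplier $\theta \ge 0$ each quantile
independently picks $\arg\min_j (p_{kj} + \theta h_{kj})$, and the total
cost of the cheapest such choice is non-increasing in $\theta$. The solver
enumerates the $O(Km^2)$ breakpoints where some row switches regimen,
binary-searches for the smallest $\theta$ whose cheap-side choice is
affordable, and then spends the remaining budget along the tie at that
$\theta$, splitting at most the final moved row fractionally. This is exact
(complementary slackness holds by construction), and explains a structural
fact the interface exploits: **an optimal solution mixes regimens in at most
one quantile per active tie**, which is precisely how a threshold lands part
way through a quantile. Feasibility tolerance is $10^{-9}$ (relative);
objective comparisons use $10^{-8}$ relative. Infeasible budgets (below the
cheapest-regimen-for-all cost) return `status = "infeasible"` rather than
an error so budget sweeps can flag and skip.

No LP library is used: none is guaranteed in the deployment environment, the
instances are tiny ($\le 100 \times 5$), and the structure admits an exact
specialized method. Correctness is established two independent ways in the
test suite: a grid brute force that exhaustively enumerates all integer
assignments plus every single-row two-regimen mixture in steps of 0.01 (a
family that contains every vertex of the feasible polytope), and
`scipy.optimize.linprog` invoked through the system Python.

**Integer programme.** `solve_ip()` gives the cohort formulation with
binary $x$. Below `enum_limit` ($m^K \le 2\times10^4$) it enumerates
exhaustively; above, it runs branch-and-bound, branching on the (unique)
fractional row of the LP relaxation. The LP objective is always a lower
bound; the population analysis never needs the IP.

**Tie-breaking.** Degenerate instances (tied risks, tied Lagrangian values)
have many optima. `canonicalize()` returns the representative in which
regimen cost is non-increasing as risk falls — sorted quantiles receive the
regimen masses in descending cost order. Because $p_{kj} = r_k c_j$ is
separable (including under every sensitivity perturbation, which only moves
$c_j$), the rearrangement inequality guarantees the objective cannot worsen,
and since the input was optimal it is exactly preserved; the function
verifies this and, for a hypothetical non-separable $p$ where it would fail,
warns and returns its input unchanged. Canonical optima are unique, which
makes the scale-invariance property testable as literal matrix equality.

**Scale invariance.** Multiplying all $r_k$ by $M > 0$ multiplies the
objective by $M$ and leaves constraints untouched, so the optimal
(canonical) assignment and the *relative* benefit are unchanged. Only the
risk model's relative calibration matters for threshold choice; this is
asserted on random instances for $M \in \{0.5, 2, 10\}$.

# Risk distribution and thresholds

`quantiles_from_scores()` uses controls only by default: in a case–control
evaluation the controls, not the case-enriched pool, represent the screened
population (a flag admits cohort samples). Quantiles are equal-count by
rank: the $i$-th cut point is the order statistic of rank
$\lceil i\,n/K \rceil$, ties spanning a cut point go to the lower quantile
by rank, and quantile means are unweighted. Consequently the weighted sum of
quantile means reproduces the sample mean exactly when $K$ divides $n$ and
to $O(1/n)$ otherwise (bin counts then differ by one).

`thresholds_from_assignment()` converts shares back to score thresholds. A
cut at cumulative population mass $c$ (in quantile units) is mapped to
`b[q] + f (b[q+1] - b[q])` where $q = \lfloor c \rfloor + 1$ and
$f = c - \lfloor c \rfloor$: linear-in-rank interpolation between the
quantile's boundary scores. How published thresholds were located within
quantiles is generally not stated by sources reporting them; we fix this
interpolation rule, document it, and expose the raw quantile boundaries so
users can apply their own convention. Non-contiguous assignments (possible
only for non-canonical optima) yield shares with a warning and no score
bounds.

# The synthetic generator

`synthesize_case_control()` emulates the one feature of case–control
risk-score data that drives this analysis: a smooth unimodal control
distribution with cases shifted toward high scores. Controls are log-normal
$(\mu, \sigma)$ truncated to $[0,1]$; cases follow the risk-proportional
tilt, density $\propto r f(r)$, sampled exactly via the identity
$r\,\mathrm{dlnorm}(r;\mu,\sigma) \propto
\mathrm{dlnorm}(r;\mu+\sigma^2,\sigma)$. The tilt is the simplest mechanism
consistent with scores being (proportional to) true short-term risks, and it
makes the case/control density ratio exactly linear through the origin —
the structure the generator's acceptance test checks.

Defaults $\mu = -3.912$, $\sigma = 0.530$ were fixed once by solving two
published anchor points for the control distribution of an imaging AI's
3-year risks — roughly 32% of the population below a score of 1.56% and 4%
above 5.06% — and are not tuned thereafter. What the generator does **not**
emulate: 1:1 matching (irrelevant here, since only the control distribution
and relative risks enter the optimization), risk-model miscalibration,
measurement error, age structure, or the empirical distribution's fine
shape. A green test on synthetic data therefore establishes that the
machinery is correct and the qualitative structure (a small intensively
screened high-risk group funded by a large relaxed low-risk group), **not**
the published population shares or benefit sizes, which depend on the real
score distribution. With the defaults, the synthetic 1/3/4-year run at equal
resources lands near a 5% / 57% / 38% split with a benefit of ~11 per 1000 —
the right shape and order of magnitude, about half the benefit reported from
real centile data.

# Evaluation and robustness

`relative_benefit()` reports $1000 (P_{\text{base}} - P^*) / P_{\text{base}}$
— advanced cancers averted per 1000 expected under baseline-for-all — with
both terms computed from the same $p$ matrix so absolute-risk scale cancels.
`resource_sweep()` re-optimizes over budgets $c \cdot K h_{\text{base}}$ for
multiples $c$ in a configurable grid defaulting to 0.6–1.6 by 0.05; the
benefit is non-decreasing in budget and plateaus once the most intensive
affordable uniform plan saturates the option set.

`run_sensitivity()` implements perturbation scenarios as **absolute**
deltas: $\pm 0.10$ on $a$ or $b$ (stage mix), and $\pm 0.05$ on the
screen-detected fraction $s$, applied *after* the closed-form model, either
to all regimens or to a named subset (e.g. degrading only the non-baseline
regimens, the case where the incumbent programme performs better than
modelled). Perturbed probabilities are clipped to $[0,1]$ with a warning and
the baseline objective is recomputed under the same perturbation. Two
consequences worth knowing: a uniform shift of $s$ adds the same constant to
every $c_j$, which leaves the optimal assignment unchanged and moves the
relative benefit only through its denominator (hence "almost unchanged");
and raising $a$ narrows the $a$–$b$ gap that screening more often exploits,
hence shrinks the benefit.

# Degenerate inputs and numerical choices

* `D = 0`: $s = 0$ by continuity; all-interval detection.
* $\lambda u \to 0$: $s \to 1$; $\lambda u \to \infty$: $s \to 0$.
* Equal risks everywhere: the objective is unique by symmetry; the reported
  assignment is the canonical one.
* Budget exactly at the cheapest-for-all cost: feasible within the
  $10^{-9}$ tolerance; below it, typed infeasibility.
* All percentage output is rounded only at the presentation layer
  (`node_positive_table()`, printed shares); every computation keeps full
  precision.
* Single seed governs all randomness (only the generator is stochastic);
  CLI runs are byte-reproducible given config and seed.

# Limitations

The model is deliberately minimal: no mortality or survival modelling, no
harms (false positives, overdiagnosis), no compliance or uptake, no costs
beyond screen counts, no age-varying thresholds, and a single projection
horizon for $r_k$ regardless of regimen. It is a screening-design triage
tool: it finds the thresholds most likely to be worth carrying into a full
health-economic simulation, and quantifies how robust that choice is to its
own parameters — robustly chosen thresholds, imprecisely estimated benefit.
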
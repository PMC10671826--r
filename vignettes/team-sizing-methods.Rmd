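---
title: "Methods: demand modelling and team-sizing principles in hhcteams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demand modelling and team-sizing principles in hhcteams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hhcteams)
```

This vignette documents the models implemented in **hhcteams**, the
assumptions behind them, the numerical choices made where the design was
genuinely open, and what the test suite does and does not establish.

## 1. The demand model

Home-care demand is organised around *cases*: periods of regular care for
one client at one qualification level (QL). A case ends operationally when
more than 30 days pass between visits (`build_cases()` uses this gap
rule). Weekly demand in hours is modelled as a discrete-time
infinite-server system with batch arrivals:

* `A` — new cases per week, mean `m_a`, variance `σ_a²`;
* `S` — LoS in whole weeks, tail `S(t) = P(S ≥ t)`, mean `m_s`, Gini
  coefficient `G_s`;
* `B` — hours of care per case-week, mean `m_g`, variance `σ_g²`, held
  constant within a case.

All three are assumed i.i.d. and mutually independent. Then

$$E[N] = \rho = m_a m_s m_g, \qquad \mathrm{Var}(N) = z\rho,$$
$$z = \frac{\sigma_g^2}{m_g} + m_g + m_g\,(1 - G_s)\Big(\frac{\sigma_a^2}{m_a} - 1\Big).$$

The Gini coefficient enters through the identity
$\sum_{t\ge1} S(t)^2 = m_s (1 - G_s)$: unequal LoS *reduces* the variance
contribution of arrival over-dispersion, because long-stay cases smooth
the arrival noise. Transient moments `E[N_t]`, `Var(N_t)` combine
Bernoulli thinning of the currently active case hours with the
partial-sum contribution of the intervening arrival cohorts; they
converge to the stationary moments as `t` grows.

**Remaining LoS of current cases.** The model needs a tail `S^r` for how
long currently active cases will still stay. Since nothing in the weekly
aggregates identifies it, the package defaults to the discrete
stationary-excess (equilibrium residual) distribution of `S`
(`stationary_excess()`), which is exact when current cases are a
steady-state snapshot; a caller with better information (e.g. elapsed
durations) can supply any tail via `current_load()`. All current cases
share one `S^r`; per-case elapsed-time conditioning is out of scope.

**Normal approximation.** Wherever a demand *distribution* (not just
moments) is needed — staffing exceedance probabilities, the skill-mix
optimizer, the scenario metrics — `N` is approximated as normal with the
moments above, the usual heavy-traffic (QED) approximation for systems
serving hundreds of weekly hours. It deteriorates for very small `ρ`.

**Square-root staffing.** `C = ρ + γ√(zρ)` with grade of service `γ`
(default 1; values 0.5–2 span lenient to strict service levels). The
probability that weekly demand exceeds `C` is then about `1 − Φ(γ)`.
Capacities are deliberately fractional: hours, not heads.

**Pooling.** Teams are pooled under independence: means add, variances
add, so `z_pool` is the demand-weighted mean of the `z_i`. Positively
correlated demand across neighbouring teams (shared epidemics, weather)
would erode the pooled gains; the package does not model correlation.

## 2. Estimation from visit records

`team_parameter_table()` estimates all model inputs from a visit file:
weekly demand series (ISO weeks, Monday-based, 0-indexed from the first
week observed), arrival moments from weekly case-start counts
(left-open cases excluded, sample variance with `n−1`), case-demand
moments over case-weeks, and the LoS via Kaplan–Meier.

Choices worth flagging:

* **LoS convention**: `LoS = end_week − start_week + 1`, so a case seen
  in a single week has LoS 1 and `E[S] > 0` always.
* **Censoring**: cases active in the first observed week have unknown
  starts and are dropped from LoS estimation by default (kept, with
  durations treated as complete and a warning, only when *no* case is
  usable); cases active in the last week enter as right-censored.
* **Weibull fit**: fitted to the KM curve by weighted least squares on
  `log(−log S(t))` vs `log t`, weights = at-risk counts — a curve fit, as
  the tail beyond the observation horizon is acknowledged to be poorly
  identified; the implied mean `m_s = ρ/(m_a m_g)` is preferred to the
  tail-integrated mean for exactly that reason.
* **Gini**: computed on the tail truncated at the horizon. For the
  geometric tail `P(S>k) = q^k` the closed form `q/(1+q)` anchors the
  unit tests.
* Whether case-demand moments should be taken per case-week or per case
  average is ambiguous in weekly aggregates; per case-week is
  implemented.

## 3. Travel, availability, contracts, manageability

**Travel** uses the square-root tour-length law
`k_l √(An) + k_c r̄ M` with defaults `k_l = 0.5` (mid-range of published
constants 0.44–0.59), `k_c = 2`, `r̄ = 0` (teams without a depot). Two
exact algebraic consequences are exposed because they carry the policy
content: merging `R` identical regions multiplies total travel by exactly
`R` (no pooling gain), and pre-assigning clients to workers costs a
factor `√M` on the tour term.

**Availability**: `M̃ ~ Binomial(M, p)` present workers, `P = M̃/M`. The
default `p = 0.79` reflects 12.5% holiday/leave plus 8.5% sick leave.
`P(P ≤ l)` uses the regularized incomplete beta function, which agrees
with the binomial CDF at integer thresholds and extends it smoothly to
fractional team sizes; the tests verify the identity exhaustively for
`M ≤ 30`.

**Contracts**: with short shifts of one day part, long shifts `a = 1.5`
times longer, full-time weeks worth `b_ft = 8` and part-time weeks
`b_pt = 5` short shifts (i.e. 4 h/6 h shifts, 32 h/20 h weeks), the
full-time fraction avoiding split shifts is bounded by
`(f0+f2)·b_pt / (b_ft − 5 + (b_pt − b_ft)(f0+f2))`, clamped to `[0, 1]`.
The inversion (`required_afternoon_fraction()`) is capped at the
all-full-time feasibility threshold `min((b_ft−5)/(b_ft−b_pt), 1−1/a)`.
Direct evaluation of the bound at an afternoon fraction of 7.3% gives
about 13%, and about 42% when 13 points of flexible administrative work
are added. Values read off plots of this bound can differ from the
closed form by a couple of percentage points; the closed form is what
the package reports, and the 80%-target inversion (≈32%) is consistent
with it.

**Manageability**: complete-graph interaction counts `M(M−1)/2`; a
mediated equal split into `k` sub-teams gives `M/2 + M²/(2k)` (fractional
sizes allowed in this form). The mediator itself adds `M` edges, which is
why `k = 1` *exceeds* the complete graph.

## 4. The skill-mix optimizer

Demand per QL `k` is `N_k ~ Normal(μ_k, σ_k²)`; capacity of a higher QL
may cover lower-QL demand. Costs `w_k` are non-decreasing in `k`, and a
staffed level must carry at least the minimum contract `ℓ`. The safety
factor `η_α` (default 2 ⇒ weekly shortfall ≤ 2.3% per level) defines the
per-level requirement `C_k + e_k ≥ μ_k + η_α σ_k`, where `e_k` is the
expected surplus trickling down from above.

With `ℓ = 0` the optimum is the backward recursion: `e_K = 0`,
`C_k = max(0, μ_k + η_α σ_k − e_k)`,
`e_{k−1} = E(C_k + e_k − N_k)^+` via the normal loss function. The
excess could alternatively be defined through a joint expectation over
all higher levels at once; the one-step chained recursion is implemented
because it is what backward induction through the normal loss function
computes, treating the inherited excess as a constant at each step.

With `ℓ > 0` the problem becomes combinatorial. The solver enumerates all
`2^K` staffed/unstaffed patterns (guarded to `K ≤ 10`; `K = 3` in
practice): within a pattern, capacities sit at their recursion lower
bounds (or `ℓ`), and when an unstaffed level is left uncovered the
lowest-indexed staffed level above it is lifted by the minimal amount,
found by root finding on the monotone excess chain. With non-decreasing
costs, lifting the cheapest (lowest) active level also has the strongest
transmission down the chain, so it dominates lifting any higher level;
the test suite checks optimality against an independent exhaustive
pattern-search oracle on random `K ≤ 3` instances to `10⁻⁶` relative
cost.

Scaling the arrival rate by `m` (demand `(mμ_k, √m σ_k)`) makes the
capacity shares converge to the demand shares — small teams must
overweight the top QL, large teams can staff to the average mix
(`ratio_curve()`).

## 5. Scenario engine

A merge scan evaluates the cumulative cluster after each merge on four
metrics: utilization `ρ/C`; availability `P(P > l)` at the implied team
size `⌈ρ/20⌉` (20 direct-care hours per worker-week); the skill-mix
deviation `Σ_k (C_k/ΣC − μ_k/Σμ)^+` from the `ℓ = 0` solution; and the
complete-graph interaction count. The weighted objective
`λ₁·util + λ₃·avail − λ₄·dev − λ₆·interactions` (defaults
`λ₁ = λ₃ = λ₄ = 1`; `λ₆` doubles as the unit conversion for the raw
count) peaks at small cluster sizes for moderate `λ₆` — with the
reference teams, at two or three teams (350–500 h/week).

Per-QL inputs for the deviation term come from per-QL case streams when
visit data are available; otherwise team totals are split by the
aggregate case mix 67/9/24% with `σ_k = √(z ρ_k)`. The merge order is
caller-supplied (geographic adjacency in practice); the package does not
optimize it. Interaction counts in the scan are always the
formula-consistent `M(M−1)/2` at the implied team size.

## 6. The synthetic generator and what the tests show

`generate_visits()` draws weekly case starts (negative binomial, Poisson
or thinned binomial, selected by the requested VMR — the demand model
depends on arrivals only through two moments, and the tests verify this
distributional robustness), assigns each case a QL, a geometric or
discretised-Weibull LoS and a gamma case demand, and materialises one
record per (case, week, day part) with the day sampled under the
weekday/weekend profile. Arrivals begin a warm-up of eight mean LoS
before week 0, so the observation window opens in steady state and
contains left-open cases exactly as a real extract would. Defaults are
the observed sector aggregates (3.6 cases/week, VMR 1.4; 3.3 h/case-week,
VMR 4; mean LoS ≈ 20 weeks; day-part mix 68.6/7.3/24.2%, renormalised
from printed percentages that sum to 100.1%; weekend dip 19.3%). Sector medians of per-team statistics are used as
generator means — a modelling choice.

The generator is also the Monte-Carlo oracle: simulating the demand sum
directly reproduces the closed-form stationary and transient moments
within three standard errors at 5 000 replications (tested at the
reference parameters of a small overdispersed team and an underdispersed
one, at 300-week recovery of all generator parameters, and at degenerate
corner cases that are exact).

What passing tests do *not* show about real data: real visit records have
within-week visit patterns, client-level correlation across cases,
seasonal and trend structure, and demand–capacity feedback (planned care
reflects what could be staffed). The generator models none of these, so
parameter recovery on synthetic data validates the estimators'
correctness, not their robustness to real-world misspecification.

## 7. Problem sizes and numerical notes

The test suite uses 300-week synthetic horizons, 5 000–10 000 Monte-Carlo
replications, exhaustive binomial checks to `M = 30`, and `K ≤ 3`
skill-mix oracle comparisons — sizes chosen so the whole suite runs in
well under a minute while keeping 3-SE assertions sharp. Root finding
uses `uniroot` at tolerance `1e-10` on monotone excess chains; LoS tails
are truncated at explicit horizons with a warning when more than `1e-3`
survival mass is cut; bound formulas clamp to their natural ranges at
degenerate denominators. Reported capacities are fractional by design.

## 8. Known limitations

* No finite-server queueing or waiting-list dynamics; admission policies
  are out of scope.
* Independence assumptions throughout (across cases, across pooled
  teams, between `S` and `B`); dependence between LoS and case intensity
  can be handled by stratifying on activity type and summing.
* Interaction counts quoted for merged clusters under other (unstated)
  team-sizing conventions will not match `M(M−1)/2` at the `⌈ρ/20⌉`
  sizing; the package always reports the formula-consistent count.
* The travel model estimates distance, not time, and ignores road
  networks and time windows.
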
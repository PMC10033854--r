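---
title: "Senescent-cell dynamics and the demography of cancer and ageing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Senescent-cell dynamics and the demography of cancer and ageing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senodem)
```

## The scientific question

Multistage models of carcinogenesis predict that cancer incidence should
keep rising with age and that large, long-lived species should get more
cancer. Neither holds empirically: incidence decelerates (and in humans,
rodents and dogs sometimes declines) at old ages, and body size does not
predict cancer prevalence across mammals (Peto's paradox). `senodem`
implements a deterministic toy model in which both patterns emerge from a
single trade-off: a damaged cell can be cleared by apoptosis — at the cost
of compensatory divisions that re-seed damage and hence future cancer —
or parked in permanent cell-cycle arrest (cellular senescence) — at the
cost of accumulating senescent cells that degrade tissue function and
drive other ageing-related mortality. Whether, and how strongly, an
organism should senesce its damaged cells is then a life-history
optimization problem.

## Model and assumptions

A single well-mixed tissue carries proportions `S_t` (senescent), `D_t`
(damaged) and `1 - S_t - D_t` (healthy, mitotic) from maturity (`t = 0`,
`S_0 = D_0 = 0`). Per time step:

* damage: `delta_t = (1 - S_t - D_t) * alpha_t * (1 + S_t^rDamageToCS)`
  with `alpha_t = min(1, alpha * t)` — genomic instability grows linearly
  with age, and senescent load feeds back on the damage rate;
* fate of damaged cells (checked in this order): apoptosis with
  probability `gamma`, then senescence entry with probability `sigma`, so
  a fraction `(1 - gamma) * sigma` senesces and `(1 - gamma) * (1 - sigma)`
  stays damaged;
* compensatory proliferation: apoptosed cells are replaced by division of
  the remaining mitotic pool, of which a share `D_t / (1 - S_t)` is
  itself damaged — apoptosis buys current integrity at the price of
  re-seeded damage. New damage arising *during* these divisions is
  neglected (second order in `alpha_t`).

Organism survival is a product of three independent per-step components:
cancer `1 - D_t^rCancerToDC`, other ageing-related causes
`1 - S_t^rSenescToCS`, and extrinsic mortality `1 - extM`. Fertility
declines linearly (`B_x = 1 - SenescRepro * x`, floored at 0) and the
fitness proxy is lifetime reproductive success,
`LRS = sum_x l_x B_x`. The model is deterministic and not spatially
structured; cells do not accumulate damage along lineages — the tissue
state is fully summarized by `(S_t, D_t)`.

## Parameters

All time quantities are in model steps (the time unit is set implicitly
by the damage-accumulation rate; across mammal-like calibrations one step
is of the order of weeks to months).

| parameter | meaning | sampled range |
|---|---|---|
| `alpha` | damage-rate slope per step | 0.000497–0.006 |
| `gamma` | apoptosis probability of a damaged cell | 0.765–0.99 |
| `rCancerToDC` | resilience-to-cancer exponent | 1–4 |
| `delta_r` | `rSenescToCS - rCancerToDC` | −1–4 |
| `rDamageToCS` | tissue resilience to senescent load | 1–10 |
| `extM` | extrinsic mortality per step | `1/extM` in `[0.5, 2.5]·e0C` |
| `SenescRepro` | fertility decline rate | 0–50% decline by age `e0C` |

The `alpha`/`gamma` box is calibrated so the *cell-line undamaged life
expectancy* `e0cl = sum_t (1 - D_t)` (computed at `sigma = 0` with no
organism death) spans roughly 100–2000 steps, and the *cancer-only life
expectancy* `e0C` (survivorship under cancer mortality alone, `sigma = 0`,
`extM = 0`) spans roughly 27–2000 steps; `attach_derived_metrics()`
reproduces these corners. `rSenescToCS` is always derived as
`rCancerToDC + delta_r`, never sampled directly, so the differential in
survival costs of the two cell fates is uniformly explored, including the
region (`delta_r < 0`) where senescence is the worse bargain.

## The sampling design (what the generator emulates)

`sample_parameter_space(n, seed)` draws one 7-dimensional Latin hypercube
(`lhs::randomLHS`), keeping one-dimensional stratification in every
dimension. Dimensions 1–5 map linearly onto the boxes above. The two
life-history dimensions are rescaled *per organism type* because their
biologically meaningful range depends on the organism's own intrinsic
longevity: an extrinsic mortality that would be negligible for a
short-lived type would dominate a long-lived one. Concretely, `extM` is
uniform on the interval for which the extrinsic-only life expectancy
`1/extM` stays within `[0.5, 2.5] * e0C`, and `SenescRepro` is uniform on
`[0, 0.5/e0C]`.

Two readings of the extrinsic-mortality design exist — uniform in `extM`
or uniform in the life expectancy `1/extM` (same support, different
marginal). The package defaults to uniform `extM` — the constraint is a
statement about which mortality levels are worth exploring, and the
mortality rate itself is the natural sampling scale for a per-step
hazard — and exposes the other variant via `ext_sampling = "e0E"`.

The generator emulates a sweep over *organism types*, not a population:
there is no individual-level stochasticity, heterogeneity or environment.
Tests passing on this sweep show that the deterministic trade-off
mechanism produces the claimed patterns across parameter space; they say
nothing about sampling variation in finite populations or about any real
species' parameter values.

## The four experiments

1. **Optimal senescence** — `optimize_sigma()` evaluates LRS on a uniform
   sigma grid containing 0 and returns the *smallest* maximizer (ties on
   flat landscapes are resolved against senescence, a conservative
   choice) and the percentage gain over `sigma = 0`, which is therefore
   never negative. The gain threshold used to define "senescence pays" is
   strictly greater than 1%.
2. **Incidence phases** — on the slope `h_t` of the unconditional
   incidence `1 - p_tC`: declining where `h_t < 0`, decelerating where
   `h_t >= 0` but the next slope is smaller (including the drop into
   negative slopes, which completes the partition), accelerating/constant
   otherwise. The evaluation window runs from age 1 to the last age with
   *captive* intrinsic survivorship `>= 1e-4`: deep enough to reach the
   late-life tail where deceleration lives, but not into numerically void
   ages. The window rule materially drives the aggregate
   deceleration/decline fractions (see Limitations).
3. **Size proxies** — `size_covariates()` emits the quantities expected
   to scale with body size: `(e0cl - e0C)/e0cl` (more cell lines, more
   cancer-prone at equal cell-line longevity), `e0E/e0C` (lower extrinsic
   mortality), and `SenescRepro * e0C`; responses are `sigma*` and the
   wild/captive prevalences. Captivity removes `extM` from the
   *demography only* — the tissue trajectory is unchanged.
4. **Senolysis** — at one uniformly drawn age in
   `[1, floor(e0_captive)]`, half the senescent cells are cleared and
   replaced by compensatory division with damaged share
   `D_a / (1 - S_a/2)` (post-removal mitotic pool, mirroring the
   replacement logic of the apoptosis recurrence); the recurrences resume
   and the cause-specific cumulative incidences (each cause acting alone,
   no extrinsic mortality — a controlled environment) are compared with
   the baseline at the baseline's own final age. A cause that never
   occurs in either arm (`D` identically 0 at `sigma = 1`) is reported as
   zero change rather than an indeterminate ratio.

## Numerical choices

* **Time indexing**: `alpha_t = alpha * t` with `t = 0, 1, 2, ...`, so the
  first step adds no damage. The convention was fixed by checking the
  calibration corners: it reproduces `e0cl(0.006, 0.765) ≈ 100`,
  `e0cl(0.000497, 0.99) ≈ 2000` and `e0C(0.006, 0.765, 1) ≈ 27` within
  10% (the `alpha * (t+1)` alternative is farther on all three).
* **Simplex safety**: `delta_t` is clamped to the healthy pool (the raw
  expression exceeds it once `alpha_t (1 + S^r) > 1`), and the
  replacement term is zeroed if `S = 1` (frozen tissue, no mitotic pool).
  With these two guards `0 <= S, D` and `S + D <= 1` are provable
  invariants, and the suite asserts them on random sweeps.
* **`0^0 = 0`** in the survival power laws: an organism with no damaged
  (senescent) cells has no cancer (ageing) mortality even at exponent 0 —
  relevant because `rSenescToCS` can reach 0 under `delta_r` sampling.
* **Truncation**: sums run until survivorship `< 1e-9` (tissue iteration:
  healthy pool `< 1e-9`) or a 50,000-step horizon; horizon-capped metrics
  carry an explicit `capped` flag (e.g. `alpha = 0` has no intrinsic
  mortality and must be flagged, not silently truncated).
* **Engine**: the recurrences are compiled (Rcpp); a literal scalar R
  transcription lives in the test helpers as an independent oracle and
  the suite requires agreement to 1e-12.
* **Type-I ANOVA order**: inputs first (in the parameter-table order),
  then derived metrics, then interactions; the order is attached to the
  result because sequential shares are order-dependent, and shares should
  be read at ranking level only. The sweep's regression vocabulary also
  carries an exact collinearity (`delta_r = rSenescToCS - rCancerToDC`),
  which the fitting layer reports as an aliased term rather than hiding.
* **Study sizes**: the packaged replication uses 1000 organism types and
  a 250-point sigma grid (the full published design used 5000 × 1000);
  at these sizes the sweep statistics are stable to about one percentage
  point across seeds, and the whole pipeline runs in seconds.

## Known limitations

* The phase-classification window is a genuine degree of freedom: the
  aggregate deceleration/decline fractions move by tens of percentage
  points as the survivorship floor varies between 0.1 and 1e-4, because
  almost every strongly-senescing type eventually decelerates *somewhere*
  in its deep tail. The packaged rule (captive survivorship `>= 1e-4`) is
  declared, fixed, and deliberately deep; cross-study comparisons of
  these two fractions should state the window explicitly.
* Deterministic proportions mean no drift, no clonal structure, no
  lineage-level mutation accumulation, and no tissue architecture; the
  senescent secretome (SASP), quiescence and immune senescence are not
  modelled. These all act on exactly the quantities this model treats as
  smooth aggregates.
* Fertility is age-linear and independent of the senescent load; cancer
  incidence is equated with cancer mortality.
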
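---
title: "Borrowing pooled controls in multi-arm preclinical screens: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Borrowing pooled controls in multi-arm preclinical screens: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolctrl)
```

This vignette is the package's account of its statistical content: the model
and its assumptions, the outlier-litter exclusion procedure, the quality
gate, the synthetic-data generator used for validation, and the numerical
and design choices made where more than one defensible option existed.

## The screening design and why borrowing helps

Each experiment in a multi-compound preclinical screen contains one saline
control group and one or more drug arms of 7–14 neonatal rats, with percent
brain-area loss (injured relative to uninjured hemisphere, in [0, 100]) as
outcome. A two-group comparison at n ≈ 10 per arm has poor power at the
residual spread these experiments exhibit. But the control condition recurs
in every experiment, accumulating a couple of hundred control animals across
a screen. Simply pooling them as if they were one group would ignore that
experiments differ in baseline severity; ignoring them wastes most of the
available information. The compromise is a linear mixed model,

$$y_{ij} \mid \alpha_i = \mu + \alpha_i + \sum_k \beta_k \,
  1\{\mathrm{Trt}_i = k\} + \varepsilon_{ij}, \qquad
  \alpha_i \sim N(0, \tau^2), \quad \varepsilon_{ij} \sim N(0, \sigma^2),$$

in which the experiment random effect $\alpha_i$ absorbs between-experiment
baseline shifts (variance $\tau^2$) while every control animal still informs
the grand control mean $\mu$ and the two variance components. Each treatment
effect $\beta_k$ (reference coding: $\beta_{\text{control}} \equiv 0$;
negative values are protective) is then estimated against the *pooled*
control evidence, shrunk appropriately by $\tau$. The concurrent-control
counterpart (`fit_concurrent()`) is the same location model restricted to
one experiment with the random effect removed — with a single experiment
$\alpha$ is unidentifiable, and dropping it is the honest single-experiment
analysis. Whether such per-experiment estimates should instead be read off
the pooled fit's contrasts is a genuinely open choice; the single-experiment
fit was chosen because it is what "versus concurrent control" means
operationally, and the two are contrasted side by side in the report rather
than conflated.

Model assumptions worth stating plainly: Gaussian errors on a bounded
percentage outcome (adequate in the moderate-injury window, questionable
near the boundaries — see the generator section), a common residual variance
across arms and experiments, additive treatment effects, and no litter term
— litters are handled by the exclusion procedure, not the model.

## Priors, propriety, and the sampler

Location parameters ($\mu$, every $\beta_k$) carry improper flat priors. For
the scale parameters two options are provided:

* `flat_on_sd` (default): $p(\sigma) \propto 1$, $p(\tau) \propto 1$ on the
  SD scale. The resulting conditionals are inverse-gamma:
  $\sigma^2 \mid \cdot \sim \mathrm{IG}\!\left(\tfrac{n-1}{2},
  \tfrac{\mathrm{SSE}}{2}\right)$ and
  $\tau^2 \mid \cdot \sim \mathrm{IG}\!\left(\tfrac{I-1}{2},
  \tfrac{\sum_i \alpha_i^2}{2}\right)$. With $I \approx 20$ experiments the
  posterior is proper and well behaved; with very few experiments the
  $\tau$ posterior becomes heavy-tailed and inflates the $\mu$ interval
  (visible as convergence flags), which is the model telling you it cannot
  estimate between-experiment spread from two or three groups.
* `half_cauchy(scale)`: the standard weakly-informative alternative for
  variance components with few groups. It is sampled by an independence
  Metropolis–Hastings step that proposes from the flat-prior inverse-gamma
  conditional and accepts with the half-Cauchy prior ratio, so the move is
  exact and typically accepts at a high rate.

The sampler is a blocked Gibbs scheme: $(\mu, \beta)$ jointly from their
Normal full conditional around the least-squares solution of the
random-effect-adjusted outcomes (the cross-product inverse and its Cholesky
factor are precomputed once); each $\alpha_i$ from its precision-weighted
Normal conditional; then the two variances. Initialization uses moment
estimates (control grand mean, group-mean differences, residual and
between-experiment SDs) with per-chain jitter scaled to the data SD, so the
chains start overdispersed. Chains run on deterministic substreams of the
master seed: runs are bit-reproducible, and chain $c$'s draws do not depend
on how many chains were requested.

Two test hooks double as analysis tools. `fixed_sigma` holds the residual SD
known, which with flat location priors makes every retained draw of
$(\mu, \beta)$ an exact draw from the closed-form Normal posterior — the
sampler's primary correctness oracle. `fixed_tau = 0` removes the random
effect, collapsing the posterior mean of $(\mu, \beta)$ onto ordinary least
squares, a second independent check.

The reporting protocol follows the trial's convention: 4 chains × 10,000
iterations, first 5,000 discarded, 20,000 retained draws, no thinning.
Convergence is monitored with split R-hat and rank-normalized bulk ESS
(Geyer initial-positive-sequence truncation); parameters with R-hat > 1.01
or ESS < 400 trigger a warning, never a silent pass.

## Decision quantities

Treatment effects are summarized by the sample 2.5th/50th/97.5th posterior
percentiles (linear interpolation between order statistics, i.e. R's
default type-7 quantile; the convention is recorded in the output since
percentile conventions differ across software). The probability of efficacy
is the plain Monte-Carlo estimate
$\Pr(\beta_k < 0 \mid \text{data}) \approx N^{-1}\sum_i 1\{\beta_k^{(i)} < 0\}$
with a *strict* inequality — draws exactly at zero (possible after file
round-trips) count as non-efficacious. Its resolution is one over the
retained draw count, which is why the full protocol's 20,000 draws matter
for reporting probabilities like 99.90%.

The per-experiment descriptive comparison (median and range per arm plus a
two-sided p-value) uses the Mann–Whitney rank-sum test: the outcome is
bounded and skewed, groups are small, and median-plus-range is the natural
accompanying summary. For combined $n \le 20$ the null distribution is
enumerated exactly over all $\binom{n}{n_1}$ assignments of the pooled
midranks (this handles ties, which the classical exact algorithm does not);
larger samples use the Normal approximation with tie and continuity
correction. A Welch t-test is available behind a flag as a sensitivity
analysis. No multiplicity adjustment is applied across compounds — a
deliberate mirror of screening practice, where Pr(efficacy) rankings feed
prioritization rather than confirmatory claims; users wanting familywise
control should apply it downstream.

## The outlier-litter exclusion procedure

Littermates share a dam, a uterine environment and often a surgery session,
so a whole litter can sit abnormally low or high. The procedure screens
control animals for such litters before any efficacy analysis:

1. **Gate.** Kruskal–Wallis across litters (midranks, tie-corrected,
   chi-square reference). If not significant at 5%, stop.
2. **Selection.** The most deviant litter $j$ by average rank
   $\bar R_i$ against the overall mean rank $(n+1)/2$.
3. **Calibration.** The contrast statistic
   $T = \left(\sum_i c_i \bar R_i / SE\right)^2$ with $c_j = -1$,
   $c_{i \ne j} = 1/(K-1)$ and
   $SE = \sqrt{\tfrac{n(n+1)}{12} \sum_i c_i^2 / n_i}$, referred to a
   permutation distribution obtained by reshuffling the pooled observations
   across litters of the original sizes; $p$ is the strict fraction of
   permuted statistics exceeding the observed $T$.
4. **Exclude and repeat** while $p \le 0.05$; a single remaining litter
   forces a stop, so at most $K - 1$ litters are ever excluded.

Design choices, each exposed as a flag rather than hard-coded:

* **Absolute versus signed deviation.** The selection rule is implemented on
  the absolute deviation $|\bar R_i - (n+1)/2|$, since the procedure's aim
  is to catch abnormally small *or* large litters; the literal one-sided
  argmax is available via `one_sided = TRUE`. Ties break toward the larger
  litter, then the lexicographically smallest label, so selection is
  deterministic.
* **Re-selection under permutation.** Within each shuffled dataset the
  deviant litter is re-selected before $T$ is computed. Freezing the
  observed litter (available via `reselect = FALSE`) calibrates a contrast
  chosen by the data against a null in which it was fixed a priori, which
  anti-conservatively ignores the selection step; re-selection is the valid
  default for a data-selected contrast.
* **Permutation mechanics.** Because every statistic in the loop is
  rank-based, shuffling raw values and re-ranking is equivalent to permuting
  the fixed midrank vector; the implementation permutes ranks, making 10,000
  permutations (the default $N$) cheap. An exhaustive mode enumerates all
  $n!/\prod_i n_i!$ assignments when that count is small, and is the oracle
  against which random mode is tested.
* **Strict inequality and ties.** The p-value keeps the strict inequality
  $1\{T_b > T\}$. When permuted statistics tie the observed one on more than
  10% of draws (e.g. near-degenerate data), a warning flags that the
  strict-inequality p-value is unstable; all-identical data stop at the gate
  ($H = 0$, $p = 1$) before this can force an exclusion.
* **Grouping key.** The procedure runs on control animals grouped by litter
  within experiment by default; `control_values_by_group()` can group by
  experiment instead, since in designs where each experiment draws on one or
  two litters the two groupings nearly coincide.

One operating characteristic deserves emphasis because the bundled workflow
demonstrates it: with many small litters (2–7 control pups each, as arises
when each experiment's 7–14 controls span several litters) and real
between-experiment spread, the Kruskal–Wallis gate has little power against
a shift confined to a single 3-pup litter — the `analysis/` workflow plants
a +25 pp litter and the procedure, correctly by its own lights, retains it.
Detection is reliable when litters are larger relative to their number: at
5 litters of 10 with one litter shifted by 4 residual SDs, the shifted
litter is excluded first in ≥ 95% of seeded runs, while under an
exchangeable null fewer than ~7% of runs exclude anything (both rates are
recomputed by the test suite and the acceptance script). Litter screening is
therefore most informative at the experiment or whole-litter scale, not for
small litter fragments.

## The quality gate

Experiments whose control group does not exhibit moderate injury are not
comparable with the rest of the screen and are removed entirely (all arms).
"Moderate" is a control-group median area loss between 35 and 50 percent,
read as the closed interval $[35, 50]$: the exclusion rule is stated as
"< 35% or > 50%", so boundary values are retained. Medians use the standard
convention (mean of the two central order statistics for even $n$). The gate
is idempotent and purely experiment-level: it never modifies retained
records.

When the outcome is derived from hemisphere areas rather than given
directly, the loss percentage is
$100 \times (1 - \sum \text{ipsi} / \sum \text{contra})$ with section areas
summed before the ratio — robust to section-size differences between the two
measured sections — and clipped below at 0 for the occasional oedematous
animal whose injured hemisphere measures larger. Averaging per-section
ratios instead of summing areas is within rounding for similar-sized
sections; the sum convention is the implemented one and is stated here so
users with strong per-section size gradients can preprocess accordingly.

## The synthetic-data generator

`simulate_trial()` samples from exactly the model the analysis assumes —
experiment effects $N(0, \tau^2)$, residuals $N(0, \sigma^2)$, additive
treatment shifts — with the trial's structure: one control plus configurable
drug arms per experiment, group sizes uniform on 7–14, litter sizes uniform
on 8–15, control and treated pups interleaved across litters (mirroring
randomization across litter and sex), sex alternating. Structural defaults
(group and litter size ranges, $\mu = 41.46$) are the screen's printed
study statistics; $\tau = 5$ and $\sigma = 12$ percentage points are the
package's own choice of realistic spread — at a grand mean near 41% they
place essentially all control outcomes inside the 0–65% band such screens
report — made once and not tuned thereafter. An optional litter-level random effect (default SD 0)
exists solely for sensitivity studies of the exclusion procedure, since the
analysis model itself has no litter term.

Per-experiment RNG substreams are derived deterministically from the master
seed, so enlarging a simulated screen appends experiments without perturbing
existing ones, and every dataset is bit-reproducible from its config.

Two honesty notes. First, a Gaussian on a percentage outcome has (small)
mass outside [0, 100]; generated outcomes are folded to the boundary and the
count recorded in provenance. Under the defaults this affects well under
0.1% of animals, so goodness-of-fit and parameter-recovery tests against the
unfolded Normal mixture hold to within that mass; `truncate_to_range = TRUE`
merely declares heavier boundary pile-up (e.g. strongly protective arms
pushing animals to 0) as intended realism rather than a safeguard. Second,
the generator emulates the *statistical* structure only: no mortality or
dropout, no surgery/hypoxia covariates, no weight or temperature effects,
no skew beyond what folding induces. Tests passing on generated data
therefore validate the machinery under the model's own assumptions; they do
not certify the Gaussian-additive model against real histology data.

## Problem sizes and numerical conventions

The test suite and acceptance script run at sizes chosen to make Monte-Carlo
error negligible relative to the tolerances they assert: the conjugate
oracle at 20,000 exact draws; parameter recovery over 50 replicate screens
of 20 experiments at 4 × 2,500-iteration chains (the Gibbs conditionals are
exact, so shorter chains cost only Monte-Carlo resolution, and one
confirmation fit runs the full 4 × 10,000 protocol); the probability-of-
efficacy oracle at 10⁶ draws; exclusion operating characteristics at 1,000
null and 200 shifted replicates with 1,000 permutations each. Degenerate
inputs are handled explicitly rather than by accident: all-equal outcomes
give $H = 0, p = 1$ at the gate; zero permutation SE errors out; empty draw
vectors error rather than return NaN; a dataset whose every experiment fails
the quality gate is an error, not an empty success.

## Known limitations

* The Gaussian location model ignores the outcome's boundedness and any
  variance–mean relationship; strongly protective compounds push mass toward
  0 where the model is misspecified.
* One shared $\beta_k$ per treatment label assumes exchangeable effects when
  a compound appears in several experiments; effect-by-experiment
  interactions are out of scope, as in the screening design itself.
* No covariates (sex, weight) and no litter term in the model; litter
  structure is addressed only through the exclusion screen, whose power at
  small litter sizes is limited (see above).
* No multiplicity adjustment across arms; rankings by Pr(efficacy) are
  prioritization devices, not confirmatory inference.
* The concurrent-control analysis discards borrowing entirely; intermediate
  choices (e.g. power priors) are not implemented.
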
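---
title: "Simulating computerized adaptive tests: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating computerized adaptive tests: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catsimr)
```

## Why simulate

A computerized adaptive test (CAT) assembles a different form for every
examinee: after each item the ability estimate is updated and the next item
is chosen to be maximally useful at that estimate. The space of possible
forms is astronomically large — an ordered selection of 30 items from a
500-item pool allows `r format_sci(count_possible_forms(500, 30))` forms —
so the analytic tools used for fixed forms (reliability indices, a single
test information curve) do not describe what any individual examinee
experiences. Monte Carlo simulation with *known* true abilities is the
standard way to evaluate a CAT design before and during operation: generate
simulees, administer the adaptive test exactly as the operational engine
would, and compare estimates against truth.

catsimr implements that loop end to end: data generation, the
administration engine, and the precision and security statistics used to
judge the result.

## The response model

Items follow the three-parameter logistic (3PL) IRT model,

$$P(\theta) = c + \frac{1-c}{1 + e^{-Da(\theta - b)}},$$

with discrimination $a > 0$, difficulty $b$, pseudo-guessing
$c \in [0, 1)$ and the logistic scaling constant $D$. Setting $c = 0$
gives the 2PL model; there is a single code path. $D$ defaults to 1.7, the
convention under which the logistic curve approximates the normal ogive;
the reference design below (SEE target 0.3, pool discriminations up to
1.2, mean test length under 17) is only attainable on this metric — with
$D = 1$ the per-item information tops out at $a^2/4 \le 0.36$ and the
required test information of $1/0.3^2 \approx 11$ would take over 30 of
the pool's very best items. $D$ is configurable in `model_settings()`.

Item Fisher information is
$I(\theta) = D^2 a^2 \frac{Q}{P}\left(\frac{P-c}{1-c}\right)^2$ (for
$c = 0$, $D^2 a^2 P Q$, maximal at $\theta = b$); the test information
function (TIF) is the sum over administered items, and the standard error
of estimation is $\mathrm{SEE} = 1/\sqrt{\mathrm{TIF}}$. The literal
reciprocal $1/\mathrm{TIF}$ is sometimes quoted for this quantity; it is
available via `see_from_tif(..., convention = "reciprocal")` for
comparison, but every default uses the square-root identity — it is the
only convention under which an SEE target of 0.3 corresponds to a
realistic test length.

## Data generation

`generate_simulees()` and `generate_item_pool()` draw from normal, uniform,
beta (with optional location–scale so bounded discriminations can be
generated) or constant specifications. The package defaults *are* the
reference study conditions: 5,000 simulees with $\theta \sim N(0,1)$ and a
300-item 2PL pool with $a \sim U(0.5, 1.2)$, $b \sim U(-3, 3)$. The
constant family supports the CSEM design that replicates thousands of
simulees at one fixed $\theta$.

Randomness is organised into four named streams — pool, simulees,
responses, selection — each an independently seeded RNG state
(`rng_stream()`). Changing the simulee seed therefore cannot perturb a
generated pool, and security analyses can vary the examinee sample while
holding the pool fixed. Within a run, every simulee gets its own response
and selection substreams derived from the master seeds and a stable key
embedded in the simulee id, so records are reproducible item by item and
invariant to batch order.

## Ability estimation

Four estimators share one Newton–Raphson core (`estimate_theta()`):

* **MLE** — maximum likelihood. The iteration uses Fisher-scoring
  curvature (identical to the observed information when $c = 0$ and
  unconditionally positive), a per-iteration step clamp of 1, and a
  bounded grid-plus-golden-section fallback if it has not met the step
  tolerance (default $10^{-4}$) within 50 iterations; the fallback is
  always reported through `converged = FALSE`. All-correct or
  all-incorrect patterns have no finite maximiser; the result is then the
  `theta_range` boundary with `finite = FALSE` so the engine can continue
  the administration (final scoring under MLEF never hits this).
* **MLEF** — MLE with fences: the likelihood is augmented with two
  imaginary 2PL items, one at the lower fence scored correct and one at
  the upper fence scored incorrect (default fences $\pm 3.5$, imaginary
  discrimination 1 on the $D$-scaled metric). This is the minimal
  construction that guarantees a finite interior maximum for *every*
  response pattern; as the fences recede the estimate converges to the
  plain MLE. The reported SEE always uses the real items only.
* **MAP** — posterior mode under a normal prior (default $N(0,1)$);
  defined for zero answered items (returns the prior mean).
* **EAP** — posterior mean by fixed-point quadrature, default 81 evenly
  spaced points on $[-4.5, 4.5]$, a grid fine enough to agree with a
  20,001-point oracle to a few times $10^{-3}$ while staying cheap inside
  the administration loop. Its `see` field carries the posterior SD.

Interim estimates pass through `apply_update_rules()`: an optional jump
limit (the reference design allows at most 1 logit of movement per item
for the first 5 items, damping early wild swings) followed by a clamp into
`theta_range` (default $[-4, 4]$).

## Item selection and exposure control

`rank_candidates()` orders the not-yet-administered items by maximized
Fisher information (MFI) at the current estimate, or by difficulty
proximity (`b_matching`), with deterministic id-order tie-breaking. The
engine's canonical selection order is:

1. content filter (constrained CAT: restrict to the area with the largest
   target-minus-administered deficit, alphabetical tie-break; if that area
   is exhausted the restriction is dropped and the record flagged),
2. criterion ranking,
3. randomesque pick — uniform among the top $k$ (default 5) candidates,
4. Sympson–Hetter filter — the picked item is administered with its
   control probability $K_j$; on rejection it becomes ineligible for this
   examinee and selection repeats. If every remaining item has been
   rejected, the pick from the full available set is administered and the
   record flagged, so administration never deadlocks.

The randomesque width applies under Sympson–Hetter control too (set
`randomesque_k = 1` there for a pure criterion pick).
`calibrate_sympson_hetter()` finds the control table by the standard
fixed-point iteration: simulate, observe per-item selection probabilities
$P(S_j)$ (selections count rejections too), set
$K_j \leftarrow \min(1, \text{target}/P(S_j))$, repeat. Each cycle uses
fresh administration seeds derived from the selection seed — with frozen
seeds the iteration replays the same realisation and oscillates instead of
converging.

## Termination

Variable-length tests stop at the first of: SEE below the threshold
(default 0.3, checked once `min_items` is reached), the score-consistency
rule (estimate moved less than `consistency_delta` for
`consistency_count` consecutive items — the rule is named in the CAT
literature without a formula; this concretisation is the package's), the
`max_items` cap (default 50, its own termination reason), or pool
exhaustion. Fixed-length mode stops at exactly `fixed_length` items.
Because selection draws are consumed in the same order regardless of the
threshold, raising the SEE threshold can only shorten tests under
identical seeds — a property the test suite asserts.

## Evaluation statistics

With true $\theta_i$ and final estimates $\hat\theta_i$ over $I$ simulees:

$$\mathrm{Bias} = \frac{1}{I}\sum_i (\hat\theta_i - \theta_i), \qquad
\mathrm{MAE} = \frac{1}{I}\sum_i |\hat\theta_i - \theta_i|, \qquad
\mathrm{RMSE} = \sqrt{\frac{1}{I}\sum_i (\hat\theta_i - \theta_i)^2}.$$

Because CAT forms differ dramatically across the ability range, the
conditional versions (CBIAS, CMAE, CRMSE, CSEE, conditional test length)
per true-$\theta$ bin are the primary diagnostics; `conditional_stats()`
computes both, with half-open bins `[low, high)`, optionally open-ended
extremes, and empty bins reported as absent rather than zero. The
count-weighted bin values recombine exactly to the overall statistics.
`csem_at_theta()` gives the CSEM point estimate — the RMSE across
replicates at one fixed $\theta$. A reliability coefficient is deliberately
not computed: a single coefficient hides exactly the conditional structure
these statistics exist to expose.

Security diagnostics (`security_summary()`): maximum exposure rate,
conditional maximum exposure per true-$\theta$ bin (conditioning is on the
*true* ability, which simulation makes available; an operational program
would have to condition on estimates), percent of the pool never used, SD
of exposure rates, and the correlation between discrimination and
exposure — the signature of information-greedy selection. The average
test-overlap index for fixed-length runs is

$$T = \frac{p\sum_j r_j^2}{k(p-1)} - \frac{1}{p-1},$$

with $r_j$ the exposure *proportion* (count/$p$) — the only reading under
which $p$ identical forms give $T = 1$ and the index equals the brute-force
mean pairwise overlap exactly (an identity the suite checks on random
cases via $\sum_j n_j(n_j-1)$ expansion). For variable-length runs the
formula is refused — its single $k$ is undefined — and
`pairwise_overlap()` is used instead, which also reports the *maximum*
pairwise overlap, since the average can mask worst cases.

## Numerical choices

* Exponent arguments are clamped to $\pm 700$ before exponentiation;
  probabilities are clipped to $[10^{-12}, 1 - 10^{-12}]$ inside
  likelihood computations only (response functions themselves are exact).
* Newton–Raphson: step clamp $\pm 1$ per iteration, tolerance $10^{-4}$,
  50-iteration cap, grid(0.01)+`optimize()` fallback over the search
  range. These safeguards guarantee termination for any response pattern.
* Ranking ties break by item id; every stochastic choice draws from a
  named stream. A full run is byte-for-byte reproducible from its config.
* Degenerate inputs error early and loudly: empty candidate sets, pools
  smaller than a fixed length, non-finite $\theta$, invalid parameter
  draws ($a \le 0$, $c \notin [0,1)$).

## What the generator does and does not emulate

The synthetic conditions reproduce the reference design faithfully:
independent uniform item parameters, normal abilities, Bernoulli
responses that follow the fitted model exactly. Real item banks violate
all three in ways that matter — parameters are calibrated with error and
are correlated (hard items tend to discriminate better), real responses
show misfit, speededness and pre-knowledge, and real populations drift
from $N(0,1)$. Passing results therefore certify the *engine and the
design logic*, not any operational pool; the package's own advice matches
standard practice: rerun the simulation with the actual calibrated pool
and the best available examinee distribution at every development stage.

## Problem sizes used in the checks

The reference reproduction runs 5,000 simulees against a 300-item pool
(about 80,000 administrations, under a minute on one core), replicated
three times with distinct seeds; stopping-rule self-consistency is
additionally checked on 1/10-scale replicates (500 simulees). Estimator
oracle equivalence uses 200 random short tests against a $10^{-4}$-step
grid search; parameter recovery uses 30-item fixed forms with 500
replicates per ability point; Sympson–Hetter calibration is exercised on a
30-item pool with 2,000 simulees and 10 cycles. These sizes were chosen so
every Monte Carlo tolerance is a 3-standard-error band at the stated n.

## Known limitations

* Unidimensional dichotomous IRT only; no polytomous or multidimensional
  models, and no item calibration from response data.
* One estimation method serves both interim and final scoring (they are
  not configured separately).
* The selection criteria and exposure-control families beyond MFI,
  b-matching, randomesque and Sympson–Hetter (a-stratification, global /
  interval / likelihood-weighted information, multinomial and fade-away
  control) are recognised names in the field but out of scope here.
* Item retirement is not scheduled; the usage table's `retirement_days`
  column is a placeholder (always 0) kept for format compatibility.
* The overlap index presumes the run used fixed-length forms; the package
  refuses rather than guesses an effective $k$.
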
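# catsimr

Monte Carlo simulation of computerized adaptive testing (CAT) under item
response theory, for psychometricians and test developers who need to
evaluate a CAT design — its measurement precision *and* its item-exposure
security — before (and while) running it operationally.

A CAT assembles a different form for every examinee: after each item the
ability estimate θ̂ is updated and the next item is chosen to suit it. An
ordered selection of 30 items from a 500-item pool already allows
3.83359E+80 possible forms (`format_sci(count_possible_forms(500, 30))`),
so fixed-form analytics do not apply and simulation with known true
abilities is the standard evaluation tool.

## What the package implements

* **Response model.** 2PL/3PL logistic IRT:
  P(θ) = c + (1 − c) / (1 + e^(−D·a·(θ − b))), Fisher item/test
  information, SEE = 1/√TIF. D defaults to 1.7.
* **Data generation.** Item pools and simulees from normal, uniform, beta
  (location–scale) or constant specifications, under four independent
  named seed streams (pool, simulees, responses, selection).
* **Ability estimation.** Newton–Raphson MLE; MLE with fences (imaginary
  boundary items keep every estimate finite); MAP; EAP by quadrature —
  with an estimate-range clamp and an early-test jump limit.
* **Item selection.** Maximized Fisher information or b-matching;
  randomesque-of-k and Sympson–Hetter exposure control (with iterative
  calibration of the control probabilities); deficit-driven content
  balancing.
* **Termination.** Fixed length, SEE threshold, score-consistency rule,
  hard item cap.
* **Evaluation.** Bias / MAE / RMSE and their conditional (per-θ-bin)
  variants, CSEE, CSEM at a fixed θ, mean conditional test length;
  exposure rates and counts, conditional maximum exposure, unused-pool
  share, SD of exposure rates, a-parameter/exposure correlation, and the
  average test-overlap index T = p·Σrⱼ²/(k(p−1)) − 1/(p−1) with its
  brute-force pairwise cross-check.

See `vignettes/cat-simulation-methods.Rmd` for the models, rules and the
reasoning behind every default.

## Worked example

The default `cat_config()` is a complete reference design: a 300-item 2PL
pool (a ~ U(0.5, 1.2), b ~ U(−3, 3)), simulees ~ N(0, 1), MFI selection
with a randomesque pick among the 5 best items, variable length stopping
at SEE < 0.3 (50-item cap), MLEF scoring with fences ±3.5, initial score
~ U(−0.5, 0.5), and the estimate jump limited to 1 for the first 5 items.

```r
library(catsimr)

cfg <- cat_config(n_simulees = 1000L)
sim <- run_simulation(cfg)
print(sim)
#> CAT simulation: 1000 simulees, pool of 300 items
#>   mean test length 15.08 (range 13-25)
#>   max exposure rate 0.537; unused items 185 (61.7%)
#>   termination: see_met=1000

conditional_stats(sim$admin, edges = seq(-3, 3, 1), open_ends = FALSE)
#> Overall precision:
#>    n     bias    mae   rmse mean_see mean_length
#>  998 0.005501 0.2437 0.3056   0.2944       15.07
#>
#> Conditional (by true-theta bin):
#>      bin   n     cbias   cmae  crmse   csee mean_length
#>  [-3,-2)  13 -0.010843 0.2310 0.2471 0.2945       16.31
#>  [-2,-1) 122 -0.002675 0.2728 0.3363 0.2952       15.59
#>   [-1,0) 376  0.019162 0.2387 0.2995 0.2943       14.62
#>    [0,1) 334  0.004383 0.2352 0.2995 0.2941       14.92
#>    [1,2) 127 -0.007685 0.2652 0.3257 0.2947       15.65
#>    [2,3)  26 -0.066741 0.1885 0.2397 0.2945       17.62

security_summary(sim)
#> Max exposure rate: 0.537 (count 537)
#> Unused items: 185 (61.7% of pool)
#> SD of exposure rates: 0.1105
#> cor(a, exposure): 0.622
```

Reading it: every simulee reached the SEE < 0.3 target (`see_met`), in
about 15 items on average; the conditional mean SEE sits just under the
0.3 target in every ability bin, and the conditional bias is near zero —
the design measures precisely and without systematic error across the
range. The security panel shows the cost of information-greedy selection:
one item went to 54% of examinees, 62% of the pool was never touched, and
exposure correlates strongly with the a-parameter. Remedies to explore in
further runs: a lower randomesque concentration, Sympson–Hetter control
(`calibrate_sympson_hetter()`), or `criterion = "b_matching"`.

Output files mirror the field's usual administration/usage logs:
`write_admin_log()`, `write_usage()`, `write_response_matrix()`,
`write_trace()` (all TSV). A thin CLI over the same functions is in
`inst/scripts/catsim` (subcommands `run`, `generate-pool`,
`generate-simulees`, `calibrate-sh`, `evaluate`) with run configs in a
flat sectioned key = value format (`read_cat_config()`).

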
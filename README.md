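# synergyscan

Statistical association scanning between drug-combination synergy and
gene- or pathway-level molecular features of cancer cell lines.

High-throughput combination screens measure how pairs of anticancer
drugs act together across dose grids in panels of tumor cell lines.
`synergyscan` implements an analysis pipeline for such screens:

1. **Synergy scoring.** Raw endpoints are converted to percent growth
   fractions anchored at a time-zero measurement,
   `Y = 100 (T1 − T0) / (T10 − T0)`, and each (drug pair, cell line) is
   scored with a modified-Bliss **ComboScore**

   `Y_AB = (1/n) Σ_{p,q} (Y_{ApBq} − Z_{ApBq})`,

   where the Bliss expectation is
   `Z_{ApBq} = min(Y_Ap, Y_Bq)` when either monotherapy growth fraction
   is non-positive and `min(Y_Ap,100)·min(Y_Bq,100)/100` otherwise.
   A combination is called synergistic in a cell line when
   `Y_AB > 10`, and a drug pair enters the association analysis when it
   is synergistic in at least five cell lines.
2. **Molecular features.** Expression presence/marginal/absent calls
   give per-cell activity calls (active iff present); DEMETER2 (D2)
   RNAi dependency scores give essentiality calls (essential iff
   D2 < −0.5). Genes are filtered (active in more than 20% of training
   cell lines, coefficient of variation ≥ 0.1, essential in at least
   one cell line), then two feature families are built per cell line:
   type 1 — drug-target counts and overlaps with active/essential
   genes; type 2 — pathway active/essential gene counts and ratios.
3. **Association scans.** Per drug pair, logistic models of synergy
   status on the features: gene-level single-predictor scans and three
   pathway analyses (PA1 = type-1 features, PA2 = type-2, PA3 = both).
   Single-predictor models report the Wald p; multi-predictor models a
   likelihood-ratio p; separated or non-convergent fits fall back to
   Firth's penalized likelihood, always flagged. P-values aggregate by
   minimum-p (per gene over pairs; per pair over pathways), with
   Bonferroni thresholds `α/m` and expected/observed **FDR tables**
   (`expected = threshold × n_tests`, `FDR = expected / observed`).
4. **Validation.** Top pathway signals are re-tested on a hold-out,
   expression-only cohort with a two-sided Wilcoxon rank-sum test on
   the pathway active-gene count between synergistic and
   non-synergistic cell lines.

A fully configurable synthetic-study generator (`simulate_study()`,
`make_fixture()`) emulates all five input types — expression + presence
calls, D2 scores, drug targets, pathway gene sets (GMT), dose-response
wells — with planted pathway-driven synergy and a ground-truth sidecar,
so every stage is testable without external data.

## Worked example

```r
library(synergyscan)

bundle  <- make_fixture("strong_signal", seed = 42)   # planted synergy
synergy <- score_synergy(bundle$dose)
head(synergy, 4)
#>   pair_id cell_line_id combo_score status n_dose_pairs
#> 1 d05_d11 TCL01            -0.760       0            9
#> 2 d05_d11 TCL02            -0.0719      0            9
#> 3 d05_d11 TCL03            -1.85        0            9
#> 4 d05_d11 TCL04            -0.996       0            9

run <- run_pipeline(bundle, tempfile("run"),
                    analyses = "PA3", modes = "expression")
dplyr::arrange(run$scans$PA3_expression$overall, overall_p) |> head(3)
#>   pair_id overall_p argmin
#> 1 d13_d19    0.0581 pw012
#> 2 d11_d15    0.0674 pw005
#> 3 d07_d10    0.0936 pw010

run$validation
#>   pair_id pathway_id cohort     n_synergy n_no_synergy statistic       p
#> 1 d13_d19 pw012      train             10           33      262  0.00438
#> 2 d13_d19 pw012      validation         5           11       46  0.0354
#> 3 d11_d15 pw005      train              7           36      212. 0.00446
#> 4 d11_d15 pw005      validation         4           12       21  0.760
```

Negative ComboScores near zero are non-synergistic background; planted
(pair, cell line) records score near +40 here and are called
synergistic. The scan's `overall_p` is each pair's minimum p over
pathways and `argmin` the pathway attaining it — for `d13_d19` the
recovered pathway `pw012` is the planted causal pathway
(`bundle$truth$causal`), and its active-gene count separates
synergistic from non-synergistic cell lines in both cohorts
(`run$validation`).

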
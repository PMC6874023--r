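# earlydisc

Challenge-style evaluation of risk predictors for **early docetaxel
discontinuation** in metastatic castration-resistant prostate cancer
(mCRPC), and simulation of the sample-size benefit of screening predicted
discontinuers out of survival trials.

About 10% of first-line mCRPC patients stop docetaxel within three months
(91.5 days) because of adverse events.  `earlydisc` rebuilds, as a tested
and reusable R pipeline, the computational machinery of a crowd-sourced
benchmarking study of this outcome:

* **Synthetic cohort generator** emulating the four source comparator
  arms (476/598/526/470 patients; early-discontinuation targets
  105/51/41/49; competing death events; latent patient risk; a
  34-team field of risk-score "submissions" with controllable skill and
  inter-team correlation).
* **Challenge scoring** — the leaderboard statistic is the area under the
  precision-recall curve (AUPRC, tie-grouped step form; for a random
  ranking its expectation sits at the outcome prevalence, ~0.104–0.115
  on the held-out composition), with AUROC secondary, one-sided empirical
  p-values against a random-model null, Benjamini–Hochberg adjustment
  (cut 0.10), and bootstrap Bayes factors (< 3 = statistically
  indistinguishable from the best model) delimiting the top-performer
  set.
* **Cumulative lift analysis** — lift at the top 5/10/20% of predicted
  risk and normalized areas under the lift-ratio curve (random model = 1).
* **Consensus risk groups** — rank-normalized scores, Manhattan/Ward
  hierarchical clustering with an elbow-selected k, concordant-high /
  concordant-low / discordant patient groups, Aalen–Johansen cumulative
  incidence of discontinuation vs death per group, and baseline-variable
  contrasts (Kruskal–Wallis / chi-squared, BH-adjusted).
* **Weighted ensemble** — per-team weights from repeated stratified 70/30
  holdout AUPRC on the training trials, applied as a weighted mean of
  rank-normalized scores.
* **Trial simulation** — balanced two-arm survival trials where latent
  discontinuers retain none of the treatment benefit; screening them out
  before randomization at sensitivity 0–100% lowers the randomized sample
  size required for 80% power at two-sided alpha 0.05, estimated by
  log-rank simulation with a Schoenfeld-anchored bisection
  (`4 (z_{1-α/2} + z_β)² / log(hr)²` events for 1:1 allocation).

The methods vignette (`vignettes/methods.Rmd`) explains every model,
default, and numerical choice.

## Worked example

```r
library(earlydisc)

# four-trial synthetic cohort at the printed sizes
co <- generate_cohort(cohort_config(seed = 1))
nrow(co)                                  # 2070
sp <- split_train_validation(co, "ENTHUSE33")
c(nrow(sp$train), nrow(sp$validation))    # 1600  470

# a 34-team field scored on the held-out trial
sm  <- generate_team_scores(co, default_team_profiles(), seed = 2)
val <- sm[match(sp$validation$patient_id, sm$patient_id), ]
y   <- as.integer(sp$validation$discontinued_early)
lb  <- rank_teams(val, y, seed = 3)
head(lb, 3)
#>   model_id auprc auroc p_value p_adjusted bayes_factor_vs_top top_performer
#> 1  team_06 0.183 0.627  0.0046     0.0867                1.00          TRUE
#> 2  team_01 0.181 0.613  0.0060     0.0867                1.15          TRUE
#> 3  team_03 0.176 0.638  0.0090     0.0867                1.25          TRUE
sum(lb$top_performer)
#> [1] 4

# lift of the best team at the top decile
lift_at(val[[lb$model_id[1]]], y, 0.10)
#> [1] 1.224138
```

Read: the best synthetic team reaches AUPRC 0.183 against a
random-model reference of ~0.104–0.115 (the prevalence level), four teams
are jointly significant (adjusted p < 0.10) and within a Bayes factor of
3 of the best, and the best team captures 1.22x as many early
discontinuers in its top decile as an unranked list would.  At 470
validation patients the size of the flagged set genuinely varies by
realization — some draws flag all seven planted strong teams, others
none; the package's tests check exact recovery of the planted tier on
2,000-patient cohorts, where it is stable.

Running the full pipeline end to end (all stages, one seed, every
artifact as CSV):

```r
run_pipeline(default_pipeline_config(seed = 1), "results")
```

The numbered drivers under `analysis/` run the same stages as a narrative
sequence (`01_cohort_and_scores.R` … `06_trial_sample_size.R`) and print
what each stage found; see the example transcript below.

```
$ Rscript analysis/06_trial_sample_size.R
required randomized sample size by hazard ratio and screening accuracy:
  hr required_n.0 required_n.1
 1.3          658          564
 1.4          444          322
 ...
 2.0          100           88
HR 1.3: screening all true discontinuers out reduces the required sample
size from 658 to 564 randomized patients
```

(Transcripts above were produced with the seeds fixed in the scripts;
`results/` is regenerated by running the drivers in order.)

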
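#!/usr/bin/env Rscript

# Stage 3 — cumulative lift-ratio analysis of every submission.
#
# For each team: lift at the top 5%, 10%, and 20% of predicted risk and
# normalized areas under the lift-ratio curve (full range and top 20%).
# A random model has lift 1 at every fraction and area 1.

library(earlydisc)

out <- "results"
run_pipeline(default_pipeline_config(seed = 1L), out,
             stages = "lift")

ls <- read.csv(file.path(out, "lift_summary.csv"))
lb <- read.csv(file.path(out, "leaderboard.csv"))
top <- lb$model_id[lb$top_performer]
if (length(top) < 2) top <- head(lb$model_id, 7)  # same fallback as pipeline
cat("lift summary, challenge top performers:\n")
print(ls[ls$model_id %in% top, ], digits = 3, row.names = FALSE)
cat("\nmean lift@10% across top performers:",
    round(mean(ls$lift_10[ls$model_id %in% top]), 2), "\n")
cat("mean AULC(20%) across top performers:",
    round(mean(ls$aulc_at_20[ls$model_id %in% top]), 2),
    "(random reference = 1)\n")
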
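#!/usr/bin/env Rscript

# Stage 6 — sample-size simulation for discontinuation-screened trials.
#
# Balanced two-arm survival trials in which 10% of patients are latent
# early discontinuers retaining none of the treatment benefit; a
# prediction model screens them out before randomization at sensitivities
# 0/25/50/75/100%.  For each hazard ratio in 1.3..2.0 the smallest
# randomized sample size reaching 80% power at two-sided alpha 0.05 is
# estimated from 100 simulated trials per power evaluation.
#
# The full 8 x 5 grid takes a while at the default replicate count; set
# EARLYDISC_FULL_GRID=1 in the environment of this script to run it all —
# the default here is the 1.3..2.0 grid at accuracies {0, 1}, which shows
# the screening effect at both ends.

library(earlydisc)

out <- "results"
cfg <- default_pipeline_config(seed = 1L)
if (!nzchar(Sys.getenv("EARLYDISC_FULL_GRID")))
  cfg$trialsim$accuracy_grid <- c(0, 1)
run_pipeline(cfg, out, stages = "trialsim")

tab <- read.csv(file.path(out, "sample_size_table.csv"))
cat("required randomized sample size by hazard ratio and screening accuracy:\n")
print(reshape(tab[c("hr", "accuracy", "required_n")],
              idvar = "hr", timevar = "accuracy", direction = "wide"),
      row.names = FALSE)
r13 <- tab[abs(tab$hr - 1.3) < 1e-9, ]
if (nrow(r13) >= 2)
  cat("\nHR 1.3: screening all true discontinuers out reduces the",
      "required sample size from", r13$required_n[r13$accuracy == 0],
      "to", r13$required_n[r13$accuracy == 1], "randomized patients\n")
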
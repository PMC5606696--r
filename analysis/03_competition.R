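#!/usr/bin/env Rscript
# Discrete-cycle competition: starting from an even Type I / Type II split,
# how many 12-h cycles does selection at each held phosphate concentration
# take to enrich the predicted winner?

suppressPackageStartupMessages(library(paokin))

dir.create("results", showWarnings = FALSE)
pair <- read_params_csv("results/synthetic/kinetic_params.csv")
manifest <- run_manifest()

all_traj <- list()
cat("Competition outcomes after 200 cycles (~100 d):\n")
for (i in seq_len(nrow(manifest))) {
  traj <- simulate_competition(pair,
                               reactor_config(aerobic_s = manifest$aerobic_p[i]),
                               n_cycles = 200)
  winner <- predicted_dominant(traj)
  final <- traj[nrow(traj), c("Type I", "Type II")]
  traj$run_id <- manifest$run_id[i]
  all_traj[[i]] <- traj
  cat(sprintf("  %s (%g mg P/L): Type I %.3f / Type II %.3f -> %s\n",
              manifest$run_id[i], manifest$aerobic_p[i],
              final[[1]], final[[2]], winner))
}
utils::write.csv(do.call(rbind, all_traj), "results/competition.csv",
                 row.names = FALSE)
cat("\nNote the slow resolution at 0.05 mg P/L: the types' rates differ by\n")
cat("~1.4% there, so selection is weak -- consistent with both types being\n")
cat("co-enriched at very low phosphate.\n")
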
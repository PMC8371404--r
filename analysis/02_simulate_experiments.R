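#!/usr/bin/env Rscript
# Simulates both slider-rating experiments at their design sizes, with a
# small injected fraction of excludable participants, runs the exclusion
# and normalization stages and writes the datasets plus exhaustivity
# summaries.  Experiment 1: one slider per state (prior arm 30, posterior
# arm 66, k in {2,3,4}).  Experiment 2: two sliders (exhaustive vs pooled
# non-exhaustive) with prior wordings none/some/all.

suppressPackageStartupMessages(library(rsafocus))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(args) >= 2 && args[1] == "--seed") args[2] else 1)
dir.create("results", showWarnings = FALSE)

behav <- response_behavior("non_normalizing", fast_frac = 0.08,
                           allzero_frac = 0.04)

arms <- list()
for (probe in c("prior", "posterior")) {
  arms[[paste0("exp1_", probe)]] <-
    generate_dataset(experiment_design(1, probe),
                     behavior = if (probe == "prior") behav
                                else response_behavior("non_normalizing"),
                     seed = seed * 13 + length(arms))
  for (pt in c("none", "some", "all")) {
    des <- experiment_design(2, probe, prior_type = pt,
                             domain_sizes = if (pt == "some") 2:4 else 2)
    arms[[paste0("exp2_", probe, "_", pt)]] <-
      generate_dataset(des, seed = seed * 13 + length(arms))
  }
}

summaries <- list()
for (nm in names(arms)) {
  excl <- apply_exclusions(arms[[nm]])
  cat(sprintf("%-22s %3d participants kept (%d fast, %d all-zero excluded)\n",
              nm,
              excl$report$n_participants[excl$report$reason == "retained"],
              excl$report$n_participants[excl$report$reason == "fast_item"],
              excl$report$n_participants[excl$report$reason == "all_zero_item"]))
  d <- normalize_responses(excl$data)
  write_slider_csv(d[, !names(d) %in% "normalized_value"],
                   file.path("results", paste0(nm, ".csv")))
  summaries[[nm]] <- cbind(arm = nm, summarize_exhaustivity(d))
}
summ <- do.call(rbind, summaries)
rownames(summ) <- NULL
write.csv(summ, "results/exhaustivity_summaries.csv", row.names = FALSE)

cat("\nExperiment 1 posterior arm (non-normalizing raters):\n")
print(summ[summ$arm == "exp1_posterior",
           c("domain_size", "mean_normalized_exh", "mean_raw_exh",
             "mean_raw_sum")], row.names = FALSE)
cat("Raw sums grow with k while raw exhaustive values stay put;\n")
cat("the normalized exhaustivity drop is produced by the denominator.\n")
cat("Wrote per-arm CSVs and results/exhaustivity_summaries.csv.\n")
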
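#!/usr/bin/env Rscript
# Step 1: generate the synthetic MPD-style cohorts used by the downstream
# analysis steps, with their ground-truth tables alongside.
#
# Two cohorts are written:
#   * with_outliers -- 2000 strain data sets across four parameters,
#     10-30 animals per sex, equal per-sex CVs, 2.3% of data sets injected
#     as high-variability outliers. This is the input for the per-parameter
#     and strain-family analyses (steps 02 and 03).
#   * female_inflated_37 -- 500 data sets at 200 animals per sex with the
#     female CV inflated by 37%; used by the calibration step (04).

suppressPackageStartupMessages(library(micecvr))

out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

for (name in c("with_outliers", "female_inflated_37")) {
  cfg <- scenario(name, seed = 20201201)
  sim <- simulate_animals(cfg)
  data_path <- file.path(out_dir, paste0(name, "_animals.tsv"))
  truth_path <- file.path(out_dir, paste0(name, "_truth.tsv"))
  write_animal_table(sim$animals, data_path)
  write_truth_table(sim$truth, truth_path)

  realized <- summarize_groups(sim$animals)
  cat(sprintf(
    "%s: %d animals in %d groups -> %s\n  configured CVs f=%.3f m=%.3f; realized median CV f=%.3f m=%.3f; %d injected outlier group(s)\n",
    name, nrow(sim$animals), nrow(sim$truth), data_path,
    cfg$cv_female_factor * cfg$cv_male, cfg$cv_male,
    median(realized$cv[realized$sex == "f"]),
    median(realized$cv[realized$sex == "m"]),
    sum(sim$truth$is_outlier)))
}
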
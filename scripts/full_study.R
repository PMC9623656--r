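#!/usr/bin/env Rscript

# Full-scale reproduction of the accuracy study: 2,000 founders, 50k SNP,
# 8,000 training cows in herds with Poisson means 1-16, six evaluation
# models, 10 replicates.  This is hours of single-core compute and several
# GB of memory; it is NOT part of the test suite.  Results land in
# results/full_study/.
#
# Usage: Rscript scripts/full_study.R [--seed N] [--replicates N] [--out DIR]

suppressPackageStartupMessages(library(smallherd))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(seed = 1L, replicates = 10L, out = "results/full_study")
i <- 1L
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  if (!key %in% c("seed", "replicates", "out")) stop("unknown arg: ", args[i])
  opt[[key]] <- if (key == "out") args[i + 1L] else as.integer(args[i + 1L])
  i <- i + 2L
}

dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
cfg <- study_config()   # full defaults

res <- run_study(cfg, n_replicates = opt$replicates, seed = opt$seed)
readr::write_csv(res, file.path(opt$out, "accuracies_long.csv"))

summ <- summarize_accuracy(res)
readr::write_csv(summ, file.path(opt$out, "accuracy_summary.csv"))
readr::write_csv(accuracy_table(summ, herd_model = "random"),
                 file.path(opt$out, "table_herd_random.csv"))

p <- plot_accuracy(dplyr::filter(summ, method == "gblup"))
ggplot2::ggsave(file.path(opt$out, "gblup_herd_models.pdf"), p,
                width = 7, height = 4.5)
message("done; outputs in ", opt$out)
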
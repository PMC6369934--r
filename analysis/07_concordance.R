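#!/usr/bin/env Rscript

# Stage 7: concordance of the two marine sub-samples.
#
# If marine allele frequencies at adaptation loci were shaped by local
# gene flow from nearby freshwater ecotypes, the two marine sub-samples
# (sampled on opposite coasts) would disagree. A major-axis regression of
# the acidic-allele frequencies at the core SNPs between the sub-samples
# with a slope near one indicates instead that these frequencies are a
# general property of the marine population.

library(afdscan)

seed <- 1
pol <- read.table("results/polarized_core.tsv", header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
sub_cols <- grep("^marine_acidic_freq_", names(pol), value = TRUE)
stopifnot(length(sub_cols) >= 2)

x <- pol[[sub_cols[1]]]
y <- pol[[sub_cols[2]]]
fit <- major_axis_fit(x, y, n_boot = 10000, seed = seed)

jsonlite::write_json(list(
  sub_samples = sub("marine_acidic_freq_", "", sub_cols[1:2]),
  slope = fit$slope, intercept = fit$intercept,
  slope_ci = c(fit$ci_low, fit$ci_high), n_points = fit$n_points
), "results/concordance.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf(paste0(
  "Major-axis regression of acidic-allele frequencies, %s vs %s,\n",
  "  at %d core SNPs: slope %.2f (95%% bootstrap CI %.2f to %.2f),\n",
  "  intercept %.3f. A slope near one indicates concordant marine\n",
  "  frequencies on both coasts.\n"),
  sub("marine_acidic_freq_", "", sub_cols[1]),
  sub("marine_acidic_freq_", "", sub_cols[2]),
  fit$n_points, fit$slope, fit$ci_low, fit$ci_high, fit$intercept))
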
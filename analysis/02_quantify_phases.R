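#!/usr/bin/env Rscript
# Detrend (60-sample rolling baseline), rectify, threshold at 0.01 MGV,
# crop at hatching and sum movement per developmental phase (myogenic
# 16-18 hAEL, neurogenic 18 hAEL to hatch) for every embryo in the
# simulated cohort.

library(embryomotion)

traces <- read_traces("results/cohort_traces.tsv")
hatch_tab <- read.delim("results/hatch_times.tsv")
hatch <- setNames(hatch_tab$hatch_time, hatch_tab$embryo)
genotype <- sub("_[0-9]+$", "", names(traces))

tab <- quantify_cohort(traces, hatch_times = hatch, genotype = genotype)
write.table(tab, "results/phase_sums.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("phase-wise movement sums (mean +/- sd, MGV-samples):\n")
agg <- aggregate(movement_sum ~ genotype + phase, tab, function(x) {
  sprintf("%8.1f +/- %6.1f", mean(x), sd(x))
})
print(agg, right = FALSE)
cat("wrote results/phase_sums.tsv\n")
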
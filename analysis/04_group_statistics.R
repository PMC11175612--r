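#!/usr/bin/env Rscript
# Group comparisons on the phase-wise movement sums: two-genotype contrasts
# (normality-gated Welch t / Mann-Whitney, Bonferroni over the two phases)
# and the three-genotype battery (Welch + Brown-Forsythe ANOVA with Dunnett
# T3, or Kruskal-Wallis with Dunn, gate-routed).

library(embryomotion)

tab <- read.delim("results/phase_sums.tsv")

two_way <- do.call(rbind, lapply(c("silenced", "mutant"), function(g) {
  do.call(rbind, lapply(c("myogenic", "neurogenic"), function(ph) {
    ctrl <- tab$movement_sum[tab$genotype == "wild_type" & tab$phase == ph]
    expt <- tab$movement_sum[tab$genotype == g & tab$phase == ph]
    r <- compare_two(list(control = ctrl, experimental = expt),
                     n_comparisons = 2)
    data.frame(contrast = paste0(g, "_vs_control"), phase = ph,
               test = r$test, statistic = r$statistic, p = r$p.value,
               p_adj = r$p.adjusted,
               normality = paste(r$normality, collapse = "/"))
  }))
}))
write.table(two_way, "results/two_group_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

neuro <- split(tab$movement_sum[tab$phase == "neurogenic"],
               tab$genotype[tab$phase == "neurogenic"])
many <- compare_many(neuro, control = "wild_type")
write.table(many$omnibus, "results/omnibus_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(many$pairwise, "results/pairwise_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("two-genotype contrasts (Bonferroni over 2 phases):\n")
print(two_way[, c("contrast", "phase", "test", "p_adj")], row.names = FALSE)
cat(sprintf("\nthree-genotype neurogenic omnibus (%s branch):\n", many$branch))
print(many$omnibus, row.names = FALSE)
cat("wrote results/two_group_tests.tsv, omnibus_tests.tsv, pairwise_tests.tsv\n")
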
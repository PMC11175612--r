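#!/usr/bin/env Rscript
# qPCR bookkeeping: amplification efficiency from a 6-point dilution
# standard curve (E = d^(-1/s), usable band 1.9-2.2) and reference-gene
# normalised fold changes from CT values.

library(embryomotion)

# synthetic standard curve: 2-fold dilutions, near-perfect doubling
set.seed(20260925)
dilution_steps <- 0:5
ct <- 18 + dilution_steps * 1.02 + round(rnorm(6, 0, 0.03), 3)
fit <- lm(ct ~ dilution_steps)        # slope per log2(dilution) step
s <- -unname(coef(fit)[2])            # CT falls as template rises
eff <- qpcr_efficiency(2, s)
cat(sprintf("standard curve slope %.3f -> efficiency E = %.3f (%s)\n",
            s, eff$efficiency,
            if (eff$in_band) "within 1.9-2.2, usable" else "out of band"))

# example CT table: gene of interest de-repressed in the mutant
cts <- data.frame(
  gene = c("target_a", "target_b"),
  goi_control = c(24.3, 22.0), goi_mutant = c(22.1, 21.9),
  ref_control = c(18.7, 18.7), ref_mutant = c(18.9, 18.9))
cts$fold_change <- mapply(qpcr_fold_change, cts$goi_control, cts$goi_mutant,
                          cts$ref_control, cts$ref_mutant)
write.table(cts, "results/qpcr_fold_changes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(cts, row.names = FALSE)
cat("wrote results/qpcr_fold_changes.tsv\n")
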
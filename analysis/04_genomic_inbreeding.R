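#!/usr/bin/env Rscript
# Stage 4: genomic inbreeding coefficients.
#
# Per individual: F_ROH over all runs, above each length threshold
# (including the pedigree-depth threshold 100/(2 GE) Mb) and within each
# length class; observed homozygosity F_HOM; the fixation index F_IS; and
# the three SNP-based F-hat estimators. Because the population is
# simulated, the coefficients are also checked against the true
# autozygous-tract fraction.

suppressPackageStartupMessages(library(rohdiv))

gm <- read_plink("results/sim/population_qc")
ped <- read_pedigree("results/sim/pedigree.tsv")
segments <- read.delim("results/roh_segments.tsv", comment.char = "#")
segments$length_bp <- segments$length_kb * 1000
s <- summarize_genotypes(gm)

ge <- equivalent_generations(ped)
ge_mean <- mean(ge[gm$samples])
tab <- f_roh_table(segments, gm$samples, L_auto = s$covered_length_bp,
                   ge_pedigree = if (ge_mean > 1) ge_mean else NULL)
tab$f_hom <- unname(f_hom(gm))
tab$f_is <- unname(f_is(gm))
tab <- cbind(tab, f_hat(gm)[, -1])
write.table(tab, "results/genomic_inbreeding.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(coef_summary(tab), "results/genomic_inbreeding_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

truth <- read.delim("results/sim/truth_f.tsv")
ft <- truth$f_true[match(tab$iid, truth$iid)]
cat(sprintf("mean F_ROH %.3f (true autozygosity %.3f); cor(F_ROH, F_true) %.3f\n",
            mean(tab$f_roh), mean(ft), cor(tab$f_roh, ft)))
cat(sprintf("pedigree depth GE = %.2f -> threshold %.3f Mb; mean F_ROH above it %.3f\n",
            ge_mean, length_from_generations(ge_mean),
            mean(tab[[grep("f_roh_gt_", names(tab), value = TRUE)[1]]])))
cat(sprintf("mean F_HOM %.3f = 1 - mean heterozygosity %.3f\n",
            mean(tab$f_hom), s$mean_heterozygosity))
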
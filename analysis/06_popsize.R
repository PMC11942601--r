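#!/usr/bin/env Rscript
# Stage 6: effective population size.
#
# Two routes: (1) LD decay, binning intra-chromosomal r-squared by distance
# and applying Ne = (1 - r2)/(4 c r2) with t = 1/(2c) generations in the
# past, overall and per birth-year cohort; (2) the closed forms on mean
# F_ROH by length threshold, dF = 1 - (1 - F)^(1/(GE_ROH - 1)) and
# Ne = 1/(2 dF), with the conventional generation constants.

suppressPackageStartupMessages(library(rohdiv))

gm <- read_plink("results/sim/population_qc")
ped <- read_pedigree("results/sim/pedigree.tsv")

birth <- ped$birth_year[match(gm$samples, ped$id)]
bins <- trend_report(gm, birth, cohort_breaks = c(2001, 2002, 2003),
                     correct_n = TRUE)
write.table(bins, "results/ne_trajectory.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

all_bins <- bins[bins$cohort == "all" & bins$n_pairs > 50 & !is.na(bins$ne), ]
recent <- all_bins[all_bins$t_generations <= 50, ]
cat(sprintf("LD trajectory: %d usable bins; Ne %.1f at ~%d generations, %.1f at ~%d\n",
            nrow(all_bins),
            recent$ne[which.max(recent$t_generations)],
            round(max(recent$t_generations)),
            recent$ne[which.min(recent$t_generations)],
            round(min(recent$t_generations))))
a <- recent[which.max(recent$t_generations), ]
b <- recent[which.min(recent$t_generations), ]
cat(sprintf("decline %.2f per generation between those points\n",
            ne_decline_rate(a$ne, b$ne, a$t_generations, b$t_generations)))

gen <- read.delim("results/genomic_inbreeding.tsv")
means <- c(mean(gen$f_roh), mean(gen$f_roh_gt_4), mean(gen$f_roh_gt_8),
           mean(gen$f_roh_gt_16), mean(gen$f_roh_gt_32))
roh_ne <- ne_from_roh_means(pmin(means, 1 - 1e-12))
write.table(roh_ne, "results/ne_from_roh.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("closed forms on mean F_ROH:\n")
print(roh_ne, digits = 4)
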
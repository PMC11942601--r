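#!/usr/bin/env Rscript
# Stage 3: calibrate and detect runs of homozygosity.
#
# The minimum run size is calibrated from the panel itself (type-I error
# 0.05 against chance runs given the observed heterozygosity), then the
# overlapping-window detector is run with the conventional settings:
# 15-SNP windows tolerating one heterozygous and one missing call, one SNP
# per 100 kb minimum density, 500 kb maximum gap.

suppressPackageStartupMessages(library(rohdiv))

gm <- read_plink("results/sim/population_qc")
s <- summarize_genotypes(gm)
cal <- min_snp_count(alpha = 0.05, het_mean = s$mean_heterozygosity,
                     n_snps = n_markers(gm), n_indiv = n_samples(gm),
                     mean_spacing_kb = s$mean_spacing_bp / 1000)
cat(sprintf("calibration: >= %d homozygous SNPs, >= %.0f kb per run\n",
            cal$min_snps, cal$min_length_kb))

params <- roh_params(min_snps_in_roh = cal$min_snps,
                     min_length_kb = cal$min_length_kb)
segments <- detect_roh(gm, params)
write_segments_tsv(segments, "results/roh_segments.tsv", params)
write_segments_bed(segments, "results/roh_segments.bed")

stats <- per_individual_stats(segments, gm$samples)
write.table(stats, "results/roh_per_individual.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
classes <- classify_lengths(segments)
write.table(classes, "results/roh_length_classes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("%d runs in %d individuals; per-individual mean %.1f runs, %.1f Mb combined\n",
            nrow(segments), sum(stats$n_roh > 0), mean(stats$n_roh),
            mean(stats$combined_length_mb)))
cat("length classes (%):",
    paste(sprintf("%s: %.1f", classes$class, classes$percent), collapse = ", "),
    "\n")
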
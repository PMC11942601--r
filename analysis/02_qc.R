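#!/usr/bin/env Rscript
# Stage 2: quality control and panel summary.
#
# Reads the PLINK files produced by 01_simulate.R, drops non-autosomal
# markers and everything below 0.90 call rate (SNPs and individuals), and
# summarizes the surviving panel: mean SNP heterozygosity, covered length
# and mean inter-SNP spacing, the three inputs of the run-length
# calibration in stage 3.

suppressPackageStartupMessages(library(rohdiv))

gm <- read_plink("results/sim/population")
qc <- apply_qc(gm, min_call_rate_snp = 0.90, min_call_rate_sample = 0.90,
               autosomes_only = TRUE, autosomes = 1:31)
write_qc_report(qc$report, "results/qc_report.tsv")
write_plink(qc$gm, "results/sim/population_qc")

s <- summarize_genotypes(qc$gm)
write.table(s$chrom, "results/panel_by_chromosome.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
panel <- data.frame(
  item = c("n_samples", "n_snps", "mean_heterozygosity",
           "covered_length_bp", "mean_spacing_bp"),
  value = c(n_samples(qc$gm), n_markers(qc$gm),
            round(s$mean_heterozygosity, 4),
            s$covered_length_bp, round(s$mean_spacing_bp)))
write.table(panel, "results/panel_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("QC: %d/%d SNPs and %d/%d individuals retained\n",
            qc$report$n_snps_after, qc$report$n_snps_before,
            qc$report$n_samples_after, qc$report$n_samples_before))
cat(sprintf("mean heterozygosity %.3f; %.1f Mb covered; %.1f kb/SNP\n",
            s$mean_heterozygosity, s$covered_length_bp / 1e6,
            s$mean_spacing_bp / 1000))
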
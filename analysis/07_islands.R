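#!/usr/bin/env Rscript
# Stage 7: consensus ROH and ROH islands.
#
# Per-SNP ROH incidence across individuals; consensus regions shared by
# 20/25/30/40/45% of the population; islands whose incidence strictly
# exceeds the genome-wide 99th percentile. Regions are exported as TSV and
# BED; a local GFF3/BED gene annotation can be joined when available.

suppressPackageStartupMessages(library(rohdiv))

gm <- read_plink("results/sim/population_qc")
segments <- read.delim("results/roh_segments.tsv", comment.char = "#")
segments$length_bp <- segments$length_kb * 1000

track <- roh_incidence(segments, gm$map, n_samples(gm))
write.table(track, "results/roh_incidence.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cons <- do.call(rbind, lapply(c(0.20, 0.25, 0.30, 0.40, 0.45),
                              function(t) consensus_roh(track, t)))
islands <- percentile_islands(track, 99)
regions <- rbind(cons, islands)
regions <- annotate_regions(regions,
                            Sys.getenv("ROHDIV_ANNOTATION", unset = ""))
write_regions_tsv(regions, "results/roh_regions.tsv")
write_regions_bed(regions, "results/roh_regions.bed")

cat(sprintf("max incidence %.2f; 99th percentile of counts %.1f\n",
            max(track$fraction), quantile(track$count, 0.99)))
for (t in c(0.20, 0.25, 0.30, 0.40, 0.45))
  cat(sprintf("consensus %d%%: %d region(s)\n", round(100 * t),
              sum(regions$kind == sprintf("consensus_%g", t))))
cat(sprintf("99th-percentile islands: %d region(s) on chromosome(s) %s\n",
            nrow(islands),
            paste(sort(unique(islands$chrom)), collapse = ", ")))
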
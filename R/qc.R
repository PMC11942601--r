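#' Apply genotype quality control
#'
#' Drops non-autosomal markers first (when `autosomes_only`), then removes
#' SNPs and samples whose call rates fall below the thresholds, repeating the
#' two rate filters until no further removal occurs so that every surviving
#' SNP and sample meets its threshold on the filtered matrix. The default
#' thresholds (0.90 for both) follow common SNP-array practice for diversity
#' studies.
#'
#' @param gm A [genotype_matrix()].
#' @param min_call_rate_snp Minimum per-SNP call rate in \[0, 1\].
#' @param min_call_rate_sample Minimum per-sample call rate in \[0, 1\].
#' @param autosomes_only Drop markers whose chromosome label is outside
#'   `autosomes`?
#' @param autosomes Vector of chromosome labels counted as autosomes.
#' @return A list with `gm` (the filtered matrix) and `report` (removed SNP
#'   ids, removed sample ids, and before/after counts).
#' @export
apply_qc <- function(gm, min_call_rate_snp = 0.90, min_call_rate_sample = 0.90,
                     autosomes_only = TRUE, autosomes = 1:31) {
  stopifnot(min_call_rate_snp >= 0, min_call_rate_snp <= 1,
            min_call_rate_sample >= 0, min_call_rate_sample <= 1)
  n_snp0 <- n_markers(gm)
  n_ind0 <- n_samples(gm)

  removed_snps <- character(0)
  if (autosomes_only) {
    keep <- gm$map$chrom %in% autosomes
    removed_snps <- gm$map$snp_id[!keep]
    if (!all(keep)) gm <- subset_gm(gm, markers = keep)
  }

  removed_samples <- character(0)
  repeat {
    miss <- is.na(gm$calls)
    cr_snp <- 1 - colMeans(miss)
    drop_snp <- cr_snp < min_call_rate_snp
    if (any(drop_snp)) {
      if (all(drop_snp)) stop("QC removed every SNP")
      removed_snps <- c(removed_snps, gm$map$snp_id[drop_snp])
      gm <- subset_gm(gm, markers = !drop_snp)
      miss <- is.na(gm$calls)
    }
    cr_ind <- 1 - rowMeans(miss)
    drop_ind <- cr_ind < min_call_rate_sample
    if (any(drop_ind)) {
      if (all(drop_ind)) stop("QC removed every sample")
      removed_samples <- c(removed_samples, gm$samples[drop_ind])
      gm <- subset_gm(gm, samples = which(!drop_ind))
    }
    if (!any(drop_snp) && !any(drop_ind)) break
  }
  if (n_markers(gm) == 0L) stop("QC removed every SNP")

  report <- list(
    removed_snps = removed_snps, removed_samples = removed_samples,
    n_snps_before = n_snp0, n_snps_after = n_markers(gm),
    n_samples_before = n_ind0, n_samples_after = n_samples(gm),
    min_call_rate_snp = min_call_rate_snp,
    min_call_rate_sample = min_call_rate_sample)
  list(gm = gm, report = report)
}

#' Write a QC report as TSV
#'
#' @param report The `report` element returned by [apply_qc()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  rows <- rbind(
    data.frame(item = "snps_before", value = report$n_snps_before),
    data.frame(item = "snps_after", value = report$n_snps_after),
    data.frame(item = "samples_before", value = report$n_samples_before),
    data.frame(item = "samples_after", value = report$n_samples_after),
    if (length(report$removed_snps))
      data.frame(item = "removed_snp", value = report$removed_snps),
    if (length(report$removed_samples))
      data.frame(item = "removed_sample", value = report$removed_samples))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarize a genotype matrix
#'
#' Per-SNP heterozygosity and call rate, per-sample call rate, and the map
#' geometry used to calibrate ROH detection: covered length per chromosome
#' (last minus first mapped position) and mean inter-SNP spacing (covered
#' length over SNP count).
#'
#' @param gm A [genotype_matrix()].
#' @return A list with `snp` (per-SNP table), `sample` (per-sample table),
#'   `chrom` (per-chromosome covered length), `covered_length_bp`,
#'   `mean_spacing_bp` and `mean_heterozygosity`.
#' @export
summarize_genotypes <- function(gm) {
  stopifnot(n_markers(gm) > 0, n_samples(gm) > 0)
  calls <- gm$calls
  het <- colMeans(calls == 1L, na.rm = TRUE)
  cr_snp <- 1 - colMeans(is.na(calls))
  cr_ind <- 1 - rowMeans(is.na(calls))

  by_chr <- split(gm$map$pos_bp, gm$map$chrom)
  single <- vapply(by_chr, length, 1L) == 1L
  if (any(single))
    warning("chromosome(s) with a single SNP have covered length 0: ",
            paste(names(by_chr)[single], collapse = ", "))
  cov_chr <- vapply(by_chr, function(p) max(p) - min(p), numeric(1))
  covered <- sum(cov_chr)

  list(
    snp = data.frame(snp_id = gm$map$snp_id, chrom = gm$map$chrom,
                     pos_bp = gm$map$pos_bp, heterozygosity = het,
                     call_rate = cr_snp, stringsAsFactors = FALSE),
    sample = data.frame(iid = gm$samples, call_rate = cr_ind,
                        stringsAsFactors = FALSE),
    chrom = data.frame(chrom = names(by_chr), n_snps = lengths(by_chr),
                       covered_bp = cov_chr, row.names = NULL,
                       stringsAsFactors = FALSE),
    covered_length_bp = covered,
    mean_spacing_bp = covered / n_markers(gm),
    mean_heterozygosity = mean(het))
}
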
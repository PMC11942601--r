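#' Minimum number of SNPs for a run of homozygosity
#'
#' Calibrates the minimum homozygous-SNP count so that fewer than `alpha`
#' runs are expected genome-wide by chance, given the panel's mean SNP
#' heterozygosity:
#' \deqn{l = \lfloor \ln(\alpha / (n_s n_i)) / \ln(1 - \bar h) \rfloor}
#' where \eqn{n_s} is the SNP count and \eqn{n_i} the number of genotyped
#' individuals. The matching minimum run length is `l` times the mean
#' inter-SNP spacing when a spacing is supplied. The count is floored, not
#' rounded: `l` is a lower bound ("l or more homozygous SNPs").
#'
#' @param alpha Type-I error rate for chance runs, in (0, 1\].
#' @param het_mean Mean per-SNP heterozygosity, strictly inside (0, 1).
#' @param n_snps Number of SNPs on the panel.
#' @param n_indiv Number of genotyped individuals.
#' @param mean_spacing_kb Optional mean inter-SNP spacing (kb) used to derive
#'   the minimum run length.
#' @return A list with `min_snps` (integer `l`) and `min_length_kb`
#'   (`NA` when no spacing is given).
#' @export
min_snp_count <- function(alpha, het_mean, n_snps, n_indiv,
                          mean_spacing_kb = NULL) {
  stopifnot(alpha > 0, alpha <= 1, n_snps >= 1, n_indiv >= 1)
  if (het_mean <= 0 || het_mean >= 1)
    stop("het_mean must be strictly between 0 and 1")
  l <- floor(log(alpha / (n_snps * n_indiv)) / log(1 - het_mean))
  l <- as.integer(l)
  list(min_snps = l,
       min_length_kb = if (is.null(mean_spacing_kb)) NA_real_
                       else l * mean_spacing_kb)
}

#' ROH detection parameters
#'
#' Bundles the overlapping-window settings. Defaults are the published
#' calibration for a ~65k equine array: 15-SNP windows allowing one
#' heterozygous and one missing call, minimum 64 SNPs and 2230 kb per run,
#' at least one SNP per 100 kb inside a run, no gap above 500 kb, and the
#' PLINK default window hit fraction of 0.05.
#'
#' @param window_snps Window size in SNPs.
#' @param max_het_in_window Heterozygous calls tolerated per window.
#' @param max_missing_in_window Missing calls tolerated per window.
#' @param min_snps_in_roh Minimum SNPs in an emitted run.
#' @param min_length_kb Minimum run length (kb).
#' @param min_density_kb_per_snp Maximum kb per SNP inside a run.
#' @param max_gap_kb Maximum inter-SNP gap inside a run (kb).
#' @param window_hit_fraction Minimum fraction of overlapping windows scored
#'   homozygous for a SNP to be run-eligible.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window_snps = 15L, max_het_in_window = 1L,
                       max_missing_in_window = 1L, min_snps_in_roh = 64L,
                       min_length_kb = 2230, min_density_kb_per_snp = 100,
                       max_gap_kb = 500, window_hit_fraction = 0.05) {
  stopifnot(window_snps >= 1, min_snps_in_roh >= 2, min_length_kb > 0,
            window_hit_fraction > 0, window_hit_fraction <= 1)
  structure(list(window_snps = as.integer(window_snps),
                 max_het_in_window = as.integer(max_het_in_window),
                 max_missing_in_window = as.integer(max_missing_in_window),
                 min_snps_in_roh = as.integer(min_snps_in_roh),
                 min_length_kb = min_length_kb,
                 min_density_kb_per_snp = min_density_kb_per_snp,
                 max_gap_kb = max_gap_kb,
                 window_hit_fraction = window_hit_fraction),
            class = "roh_params")
}

# rolling sum of x over windows of w consecutive entries
roll_sum <- function(x, w) {
  cs <- c(0, cumsum(x))
  cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]
}

# eligible SNPs for one individual on one chromosome (NULL if none)
snp_eligibility <- function(g, p) {
  L <- length(g)
  w <- p$window_snps
  if (L < w) return(rep(FALSE, L))
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  ok <- roll_sum(het, w) <= p$max_het_in_window &
        roll_sum(mis, w) <= p$max_missing_in_window
  nw <- L - w + 1L
  i <- seq_len(L)
  lo <- pmax(1L, i - w + 1L)           # first window overlapping SNP i
  hi <- pmin(nw, i)                    # last window overlapping SNP i
  cs <- c(0, cumsum(ok))
  hits <- cs[hi + 1L] - cs[lo]
  hits / (hi - lo + 1L) >= p$window_hit_fraction
}

# segments from one eligibility vector + positions; applies gap split and
# the count/length/density filters
runs_to_segments <- function(elig, pos, g, p, strict = FALSE) {
  r <- rle(elig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- vector("list", 0L)
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    gaps <- diff(pos[idx])
    piece <- cumsum(c(0L, gaps > p$max_gap_kb * 1000))
    for (part in split(idx, piece)) {
      n <- length(part)
      len <- pos[part[n]] - pos[part[1]] + 1
      if (n < p$min_snps_in_roh) next
      if (len < p$min_length_kb * 1000) next
      if (len / 1000 / n > p$min_density_kb_per_snp) next
      if (strict && sum(g[part] == 1L, na.rm = TRUE) > p$max_het_in_window) next
      out[[length(out) + 1L]] <-
        c(start = pos[part[1]], end = pos[part[n]], n = n)
    }
  }
  out
}

#' Detect runs of homozygosity
#'
#' Overlapping-window scan per individual and chromosome: every contiguous
#' window of `window_snps` SNPs is scored homozygous iff it contains at most
#' `max_het_in_window` heterozygous and `max_missing_in_window` missing
#' calls; a SNP is run-eligible iff at least `window_hit_fraction` of the
#' windows overlapping it are homozygous; maximal runs of eligible SNPs are
#' split at gaps above `max_gap_kb` and emitted when they satisfy the SNP
#' count, length and density minima. Chromosomes shorter than one window
#' yield no segments.
#'
#' @param gm A QC-passed [genotype_matrix()].
#' @param params A [roh_params()] object.
#' @param strict Additionally require at most `max_het_in_window`
#'   heterozygous calls in each emitted segment (sensitivity analysis;
#'   off by default, matching the window-only rule).
#' @return A data frame of class `roh_segments` with columns `iid`, `chrom`,
#'   `start_bp`, `end_bp`, `n_snps`, `length_bp`; zero rows when nothing is
#'   detected. Individual and chromosome processing order do not affect the
#'   result.
#' @export
detect_roh <- function(gm, params = roh_params(), strict = FALSE) {
  stopifnot(inherits(params, "roh_params"))
  chroms <- split(seq_len(n_markers(gm)), gm$map$chrom)
  res <- list()
  for (ci in chroms) {
    pos <- gm$map$pos_bp[ci]
    chrom <- gm$map$chrom[ci[1]]
    sub <- gm$calls[, ci, drop = FALSE]
    for (s in seq_len(nrow(sub))) {
      g <- sub[s, ]
      elig <- snp_eligibility(g, params)
      if (!any(elig)) next
      segs <- runs_to_segments(elig, pos, g, params, strict = strict)
      for (sg in segs)
        res[[length(res) + 1L]] <- data.frame(
          iid = gm$samples[s], chrom = chrom,
          start_bp = sg[["start"]], end_bp = sg[["end"]],
          n_snps = as.integer(sg[["n"]]),
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(iid = character(0), chrom = integer(0), start_bp = numeric(0),
               end_bp = numeric(0), n_snps = integer(0))
  out$length_bp <- out$end_bp - out$start_bp + 1
  out <- out[order(out$iid, out$chrom, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("roh_segments", "data.frame")
  out
}

#' Tabulate ROH by length class
#'
#' Counts and length moments per half-open length class `[lo, hi)` in Mb.
#' The default classes partition everything above the minimum detectable
#' length: 2-4, 4-8, 8-16, 16-32 and >32 Mb.
#'
#' @param segments A `roh_segments` data frame.
#' @param breaks_mb Increasing class boundaries in Mb; the final class is
#'   open-ended.
#' @param by_chrom Also return the per-chromosome breakdown?
#' @return A data frame with `class`, `n`, `percent`, `mean_mb`, `sd_mb`,
#'   `min_mb`, `max_mb` (plus a `by_chrom` attribute when requested).
#'   Percentages sum to 100 whenever any segment exists.
#' @export
classify_lengths <- function(segments, breaks_mb = c(2, 4, 8, 16, 32),
                             by_chrom = FALSE) {
  labels <- c(paste0(breaks_mb[-length(breaks_mb)], "-", breaks_mb[-1]),
              paste0(">", breaks_mb[length(breaks_mb)]))
  len_mb <- segments$length_bp / 1e6
  cls <- cut(len_mb, c(breaks_mb, Inf), labels = labels, right = FALSE)
  tab_one <- function(cl, lm) {
    n <- as.integer(table(cl))
    data.frame(
      class = labels, n = n,
      percent = if (sum(n)) 100 * n / sum(n) else rep(0, length(n)),
      mean_mb = as.numeric(tapply(lm, cl, mean)),
      sd_mb = as.numeric(tapply(lm, cl, stats::sd)),
      min_mb = as.numeric(tapply(lm, cl, min)),
      max_mb = as.numeric(tapply(lm, cl, max)),
      stringsAsFactors = FALSE)
  }
  out <- tab_one(cls, len_mb)
  if (by_chrom && nrow(segments))
    attr(out, "by_chrom") <- do.call(rbind, lapply(
      split(seq_len(nrow(segments)), segments$chrom),
      function(i) cbind(chrom = segments$chrom[i[1]],
                        tab_one(cls[i], len_mb[i]))))
  out
}

#' Percentages of segment counts by class
#'
#' Utility used when only class counts are at hand.
#'
#' @param counts Integer vector of per-class segment counts.
#' @return Percentages summing to 100.
#' @export
class_percentages <- function(counts) {
  stopifnot(all(counts >= 0), sum(counts) > 0)
  100 * counts / sum(counts)
}

#' Per-individual ROH statistics
#'
#' Number of runs, mean run length and combined run length per individual.
#' Individuals without any run report zeros, so the full sample list is
#' required.
#'
#' @param segments A `roh_segments` data frame.
#' @param samples Character vector of all individual ids.
#' @return A data frame with `iid`, `n_roh`, `mean_length_mb`,
#'   `combined_length_mb`.
#' @export
per_individual_stats <- function(segments, samples) {
  idx <- factor(segments$iid, levels = samples)
  n <- as.integer(table(idx))
  comb <- as.numeric(tapply(segments$length_bp, idx, sum))
  comb[is.na(comb)] <- 0
  data.frame(iid = samples, n_roh = n,
             mean_length_mb = ifelse(n > 0, comb / n / 1e6, 0),
             combined_length_mb = comb / 1e6,
             stringsAsFactors = FALSE)
}

#' Export ROH segments
#'
#' TSV keeps 1-based inclusive coordinates; BED uses 0-based half-open.
#'
#' @param segments A `roh_segments` data frame.
#' @param path Output file.
#' @param params Optional [roh_params()] echoed into a `#` header line.
#' @return `path`, invisibly.
#' @export
write_segments_tsv <- function(segments, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params))
    writeLines(paste0("# roh_params: ",
                      paste(names(params), unlist(params), sep = "=",
                            collapse = " ")), con)
  df <- data.frame(iid = segments$iid, chrom = segments$chrom,
                   start_bp = segments$start_bp, end_bp = segments$end_bp,
                   n_snps = segments$n_snps,
                   length_kb = segments$length_bp / 1000)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments_tsv
#' @export
write_segments_bed <- function(segments, path) {
  utils::write.table(
    data.frame(segments$chrom, segments$start_bp - 1, segments$end_bp,
               segments$iid),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
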
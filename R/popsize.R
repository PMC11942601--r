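#' Intra-chromosomal pairwise linkage disequilibrium
#'
#' Squared Pearson correlation of genotype dosages for every pair of SNPs on
#' the same chromosome whose distance lies in `[min_bp, max_bp]`, computed
#' over the individuals complete for both SNPs. Pairs involving a
#' zero-variance SNP are skipped.
#'
#' @param gm A [genotype_matrix()].
#' @param min_bp,max_bp Distance window in bp (defaults 1 kb to 50 Mb).
#' @param correct_n Subtract the small-sample bias `1/n` (pairwise complete
#'   `n`) from each r-squared? Off by default: the plain dosage correlation
#'   is reported unless small samples make the `~1/n` inflation material.
#' @return Data frame with `chrom`, `dist_bp`, `r2`.
#' @export
pairwise_r2 <- function(gm, min_bp = 1e3, max_bp = 50e6, correct_n = FALSE) {
  out <- list()
  for (ci in split(seq_len(n_markers(gm)), gm$map$chrom)) {
    if (length(ci) < 2L) next
    x <- gm$calls[, ci, drop = FALSE]
    pos <- gm$map$pos_bp[ci]
    v <- apply(x, 2, stats::var, na.rm = TRUE)
    ok <- !is.na(v) & v > 0
    if (sum(ok) < 2L) next
    x <- x[, ok, drop = FALSE]
    pos <- pos[ok]
    cc <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
    dist <- abs(outer(pos, pos, "-"))
    sel <- upper.tri(dist) & dist >= min_bp & dist <= max_bp & !is.na(cc)
    r2 <- cc[sel]^2
    if (correct_n) {
      npair <- crossprod(!is.na(x))
      r2 <- pmax(0, r2 - 1 / npair[sel])
    }
    out[[length(out) + 1L]] <- data.frame(
      chrom = gm$map$chrom[ci[1]], dist_bp = dist[sel], r2 = r2)
  }
  if (!length(out))
    return(data.frame(chrom = integer(0), dist_bp = numeric(0), r2 = numeric(0)))
  do.call(rbind, out)
}

#' Default LD distance bins
#'
#' Bin widths grow from 10 kb at the near end to 100 kb, then geometrically
#' up to the far bound, so recent generations (large distances) are resolved
#' without starving distant-generation bins of pairs.
#'
#' @param min_bp,max_bp Range covered by the bins.
#' @return Numeric vector of bin edges.
#' @export
default_bin_edges <- function(min_bp = 1e4, max_bp = 50e6) {
  edges <- min_bp
  width <- 1e4
  while (edges[length(edges)] < max_bp) {
    edges <- c(edges, edges[length(edges)] + width)
    width <- min(1e5, width * 1.25)
  }
  edges[edges <= max_bp]
}

#' Bin LD pairs and estimate Ne per distance bin
#'
#' Per half-open bin `[lo, hi)`: mean r-squared, pair count, recombination
#' distance `c` (bin midpoint in units of 100 Mb = 1 Morgan), generations in
#' the past `t = 1/(2c)`, effective size `Ne = (1 - r2)/(4 c r2)` and rate
#' of inbreeding `dF = 1/(2 Ne)`. Empty bins are emitted with `n_pairs = 0`
#' and undefined estimates.
#'
#' @param pairs Data frame from [pairwise_r2()].
#' @param bin_edges Increasing bin edges in bp.
#' @return Data frame of class `ld_bins` with one row per bin.
#' @export
bin_and_estimate <- function(pairs, bin_edges = default_bin_edges()) {
  stopifnot(!is.unsorted(bin_edges, strictly = TRUE))
  nb <- length(bin_edges) - 1L
  bin <- findInterval(pairs$dist_bp, bin_edges, rightmost.closed = FALSE)
  keep <- bin >= 1L & bin <= nb
  bin <- factor(bin[keep], levels = seq_len(nb))
  mean_r2 <- as.numeric(tapply(pairs$r2[keep], bin, mean))
  n_pairs <- as.integer(table(bin))
  mid <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  cM <- mid / 1e8                       # Morgans at 100 Mb per Morgan
  ne <- ifelse(n_pairs > 0 & mean_r2 > 0, (1 - mean_r2) / (4 * cM * mean_r2),
               NA_real_)
  out <- data.frame(dist_lo = bin_edges[-length(bin_edges)],
                    dist_hi = bin_edges[-1],
                    mean_r2 = mean_r2, n_pairs = n_pairs,
                    c_morgan = cM, t_generations = 1 / (2 * cM),
                    ne = ne, delta_f = ifelse(is.na(ne) | ne <= 0,
                                              NA_real_, 1 / (2 * ne)))
  class(out) <- c("ld_bins", "data.frame")
  out
}

#' LD-decay Ne trajectory in one call
#'
#' Convenience wrapper chaining [pairwise_r2()] and [bin_and_estimate()]
#' chromosome by chromosome without keeping all pairs in memory.
#'
#' @inheritParams pairwise_r2
#' @param bin_edges Passed to [bin_and_estimate()].
#' @return An `ld_bins` data frame.
#' @export
ld_ne <- function(gm, bin_edges = default_bin_edges(), min_bp = 1e3,
                  max_bp = 50e6, correct_n = FALSE) {
  nb <- length(bin_edges) - 1L
  sums <- numeric(nb)
  counts <- integer(nb)
  for (ch in unique(gm$map$chrom)) {
    sub <- subset_gm(gm, markers = gm$map$chrom == ch)
    pr <- pairwise_r2(sub, min_bp, max_bp, correct_n = correct_n)
    if (!nrow(pr)) next
    bin <- findInterval(pr$dist_bp, bin_edges)
    keep <- bin >= 1L & bin <= nb
    if (any(keep)) {
      bs <- rowsum(pr$r2[keep], bin[keep])
      sums[as.integer(rownames(bs))] <- sums[as.integer(rownames(bs))] + bs[, 1]
      counts <- counts + tabulate(bin[keep], nb)
    }
  }
  fake <- data.frame(chrom = integer(0), dist_bp = numeric(0), r2 = numeric(0))
  out <- bin_and_estimate(fake, bin_edges)
  out$n_pairs <- counts
  out$mean_r2 <- ifelse(counts > 0, sums / counts, NA_real_)
  out$ne <- ifelse(counts > 0 & out$mean_r2 > 0,
                   (1 - out$mean_r2) / (4 * out$c_morgan * out$mean_r2),
                   NA_real_)
  out$delta_f <- ifelse(is.na(out$ne) | out$ne <= 0, NA_real_, 1 / (2 * out$ne))
  out
}

#' Ne and dF closed forms from mean F_ROH
#'
#' For each length threshold, the rate of inbreeding is
#' \deqn{\Delta F = 1 - (1 - \bar F_{ROH})^{1/(GE_{ROH} - 1)}}
#' with `GE_ROH` the number of generations captured by runs above the
#' threshold, and `Ne = 1/(2 dF)`. The conventional generation constants for
#' thresholds (all, >4, >8, >16, >32 Mb) are 15.6691, 12.5, 6.25, 3.125 and
#' 1.5625.
#'
#' @param f_roh_means Mean F_ROH per threshold, each in \[0, 1).
#' @param ge_constants Generations captured, one per threshold, all > 1.
#' @param labels Optional threshold labels.
#' @return Data frame with `threshold`, `f_roh_mean`, `ge_roh`,
#'   `delta_f_roh`, `ne_roh` (`NA` Ne when F_ROH is 0).
#' @export
ne_from_roh_means <- function(f_roh_means,
                              ge_constants = c(15.6691, 12.5, 6.25, 3.125, 1.5625),
                              labels = c("all", ">4", ">8", ">16", ">32")) {
  stopifnot(length(f_roh_means) == length(ge_constants),
            all(f_roh_means >= 0), all(f_roh_means < 1))
  if (any(ge_constants <= 1)) stop("ge_constants must exceed 1")
  df <- 1 - (1 - f_roh_means)^(1 / (ge_constants - 1))
  data.frame(threshold = labels[seq_along(f_roh_means)],
             f_roh_mean = f_roh_means, ge_roh = ge_constants,
             delta_f_roh = df,
             ne_roh = ifelse(df > 0, 1 / (2 * df), NA_real_),
             stringsAsFactors = FALSE)
}

#' Ne from a rate of inbreeding
#'
#' Inverts `dF = 1/(2 Ne)`.
#'
#' @param delta_f Per-generation rate(s) of inbreeding.
#' @return `1/(2 delta_f)`; `NA` (with a warning) where `delta_f <= 0`.
#' @export
ne_from_delta_f <- function(delta_f) {
  bad <- !is.na(delta_f) & delta_f <= 0
  if (any(bad)) warning("Ne undefined for delta_f <= 0")
  ifelse(bad, NA_real_, 1 / (2 * delta_f))
}

#' Date ROH length in generations (and back)
#'
#' Under a 1 cM/Mb map, a run of expected length `L` Mb reflects a common
#' ancestor about `g = 100/(2 L)` generations back; the inverse gives the
#' expected run length for inbreeding `g` generations ago.
#'
#' @param len_mb Run length in Mb (positive).
#' @return Generations in the past.
#' @export
generations_from_length <- function(len_mb) {
  if (any(len_mb <= 0)) stop("length must be positive")
  100 / (2 * len_mb)
}

#' @rdname generations_from_length
#' @param g Generations in the past (positive).
#' @export
length_from_generations <- function(g) {
  if (any(g <= 0)) stop("generations must be positive")
  100 / (2 * g)
}

#' Per-generation decline in Ne between two trajectory points
#'
#' @param ne_a,ne_b Ne at the earlier (`g_a`) and later (`g_b`) generation,
#'   with `g_a > g_b` (generations counted backwards in time; 0 = present).
#' @return `(ne_a - ne_b) / (g_a - g_b)`.
#' @export
ne_decline_rate <- function(ne_a, ne_b, g_a, g_b) {
  stopifnot(g_a > g_b)
  (ne_a - ne_b) / (g_a - g_b)
}

#' Cohort Ne/dF trajectories
#'
#' Runs the LD-decay estimator per birth-year cohort and stacks the
#' trajectories. Cohorts with fewer than `min_cohort` individuals are
#' skipped with a warning.
#'
#' @param gm A [genotype_matrix()].
#' @param birth_years Numeric vector, one per individual in `gm`.
#' @param cohort_breaks Right-closed cut points for the cohorts; defaults
#'   split at 2007, 2011, 2015 and 2019.
#' @param bin_edges,correct_n Passed to [ld_ne()].
#' @param min_cohort Minimum cohort size.
#' @return An `ld_bins` data frame with an extra `cohort` column (the
#'   overall trajectory is labeled `"all"`).
#' @export
trend_report <- function(gm, birth_years = NULL,
                         cohort_breaks = c(2007, 2011, 2015, 2019),
                         bin_edges = default_bin_edges(),
                         correct_n = FALSE, min_cohort = 2L) {
  all_bins <- ld_ne(gm, bin_edges, correct_n = correct_n)
  all_bins$cohort <- "all"
  out <- list(all_bins)
  if (!is.null(birth_years)) {
    stopifnot(length(birth_years) == n_samples(gm))
    br <- c(-Inf, cohort_breaks, Inf)
    lab <- c(paste0("<=", cohort_breaks[1]),
             paste0(cohort_breaks[-length(cohort_breaks)] + 1, "-",
                    cohort_breaks[-1]),
             paste0(">=", cohort_breaks[length(cohort_breaks)] + 1))
    cohort <- cut(birth_years, br, labels = lab)
    for (cl in levels(cohort)) {
      sel <- which(!is.na(cohort) & cohort == cl)
      if (length(sel) < min_cohort) {
        warning("cohort ", cl, " has fewer than ", min_cohort,
                " individuals; skipped")
        next
      }
      b <- ld_ne(subset_gm(gm, samples = sel), bin_edges, correct_n = correct_n)
      b$cohort <- cl
      out[[length(out) + 1L]] <- b
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("ld_bins", "data.frame")
  res
}
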
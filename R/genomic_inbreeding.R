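#' Genomic inbreeding from ROH coverage
#'
#' For each individual, the summed length of its runs of homozygosity
#' within the stated length bound, divided by the total autosomal length
#' covered by SNPs. The default `L_auto` is the covered length of the ~65k
#' equine array panel; pass the covered length of your own panel (see
#' [summarize_genotypes()]).
#'
#' @param segments A `roh_segments` data frame.
#' @param samples Character vector of all individual ids (individuals with
#'   no run report 0).
#' @param L_auto Total autosomal length covered by SNPs, in bp.
#' @param min_len_mb,max_len_mb Half-open length bound `[min, max)` in Mb;
#'   defaults include every segment.
#' @return Named numeric vector of F_ROH per individual.
#' @export
f_roh <- function(segments, samples, L_auto = 2241761617, min_len_mb = 0,
                  max_len_mb = Inf) {
  stopifnot(L_auto > 0)
  if (min_len_mb < 0 || max_len_mb < min_len_mb)
    stop("invalid length bound")
  len <- segments$length_bp / 1e6
  keep <- len >= min_len_mb & len < max_len_mb
  idx <- factor(segments$iid[keep], levels = samples)
  tot <- tapply(segments$length_bp[keep], idx, sum)
  tot[is.na(tot)] <- 0
  stats::setNames(as.numeric(tot) / L_auto, samples)
}

#' All F_ROH variants per individual
#'
#' F_ROH over all runs, above each length threshold, and within each length
#' class. The generation-linked threshold (by default 100 / (2 GE) Mb with
#' GE = 7.42, i.e. 6.739 Mb) captures runs younger than the available
#' pedigree depth; pass `ge_pedigree = NULL` to skip it.
#'
#' @inheritParams f_roh
#' @param thresholds_mb Lower thresholds (Mb) for the `f_roh_gt_*` columns.
#' @param class_breaks_mb Class boundaries (Mb) for the half-open
#'   `f_roh_class_*` columns; the final class is open-ended and equals
#'   `f_roh_gt_` at the last break.
#' @param ge_pedigree Equivalent generations of the accompanying pedigree,
#'   used to insert the threshold `100 / (2 ge_pedigree)` Mb.
#' @return Data frame, one row per individual.
#' @export
f_roh_table <- function(segments, samples, L_auto = 2241761617,
                        thresholds_mb = c(4, 8, 16, 32),
                        class_breaks_mb = c(2, 4, 8, 16, 32),
                        ge_pedigree = 7.42) {
  out <- data.frame(iid = samples,
                    f_roh = f_roh(segments, samples, L_auto),
                    stringsAsFactors = FALSE)
  thr <- sort(unique(c(thresholds_mb,
                       if (!is.null(ge_pedigree))
                         length_from_generations(ge_pedigree))))
  for (t in thr)
    out[[paste0("f_roh_gt_", round(t, 3))]] <-
      f_roh(segments, samples, L_auto, min_len_mb = t)
  ends <- c(class_breaks_mb[-1], Inf)
  for (k in seq_along(class_breaks_mb))
    out[[paste0("f_roh_class_", class_breaks_mb[k], "_", ends[k])]] <-
      f_roh(segments, samples, L_auto, class_breaks_mb[k], ends[k])
  rownames(out) <- NULL
  out
}

#' Observed homozygosity per individual
#'
#' Fraction of non-missing calls that are homozygous. On complete data its
#' sample mean equals one minus the mean SNP heterozygosity.
#'
#' @param gm A [genotype_matrix()].
#' @return Named numeric vector; `NA` (with a warning) for individuals with
#'   no non-missing call.
#' @export
f_hom <- function(gm) {
  hom <- rowSums(gm$calls != 1L, na.rm = TRUE)
  nn <- rowSums(!is.na(gm$calls))
  if (any(nn == 0L)) warning("individual(s) with no non-missing call")
  stats::setNames(ifelse(nn > 0L, hom / nn, NA_real_), gm$samples)
}

#' Individual fixation index F_IS
#'
#' One minus the ratio of an individual's observed heterozygous calls to its
#' expected count under Hardy-Weinberg, \eqn{\sum_j 2 p_j (1 - p_j)} over
#' its non-missing SNPs, with allele frequencies taken from the full sample
#' (focal individual included).
#'
#' @param gm A [genotype_matrix()].
#' @return Named numeric vector; positive values mark homozygosity excess.
#' @export
f_is <- function(gm) {
  p <- allele_freq(gm)
  exp_het <- 2 * p * (1 - p)
  notna <- !is.na(gm$calls)
  expd <- notna %*% exp_het
  if (all(expd == 0)) stop("panel is monomorphic; F_IS undefined")
  obs <- rowSums(gm$calls == 1L, na.rm = TRUE)
  stats::setNames(as.numeric(1 - obs / expd), gm$samples)
}

#' SNP-based inbreeding estimators F-hat 1-3
#'
#' The three GCTA-style estimators, with sample allele frequencies `p` and
#' dosage `x`:
#' \deqn{\hat F_1 = \mathrm{mean}_j[(x - 2p)^2/(2p(1-p))] - 1}
#' (diagonal of the genomic relationship matrix), \eqn{\hat F_2 = 1 -
#' \mathrm{mean}_j[x(2-x)/(2p(1-p))]} (homozygosity excess) and
#' \eqn{\hat F_3 = \mathrm{mean}_j[(x^2 - (1+2p)x + 2p^2)/(2p(1-p))]}
#' (correlation of uniting gametes). Monomorphic SNPs are excluded; means
#' run over each individual's non-missing SNPs.
#'
#' @param gm A [genotype_matrix()].
#' @return Data frame with `iid`, `f_hat1`, `f_hat2`, `f_hat3`.
#' @export
f_hat <- function(gm) {
  p <- allele_freq(gm)
  keep <- !is.na(p) & p > 0 & p < 1
  x <- gm$calls[, keep, drop = FALSE]
  p <- p[keep]
  if (!length(p)) stop("no polymorphic SNP; F-hat undefined")
  denom <- 2 * p * (1 - p)
  n_ind <- nrow(x)
  P2 <- matrix(2 * p, n_ind, length(p), byrow = TRUE)
  D <- matrix(denom, n_ind, length(p), byrow = TRUE)
  t1 <- (x - P2)^2 / D
  t2 <- x * (2 - x) / D
  t3 <- (x^2 - (1 + P2) * x + P2^2 / 2) / D
  m <- function(z) rowMeans(z, na.rm = TRUE)
  data.frame(iid = gm$samples,
             f_hat1 = m(t1) - 1,
             f_hat2 = 1 - m(t2),
             f_hat3 = m(t3),
             stringsAsFactors = FALSE)
}

#' Summary table of inbreeding coefficients
#'
#' Mean, SD, median, mode (most frequent value after rounding) and central
#' 95% / 75% intervals, one row per coefficient column.
#'
#' @param df Data frame of per-individual coefficients (non-numeric columns
#'   ignored).
#' @param digits Rounding used for the empirical mode.
#' @return Data frame, one row per coefficient.
#' @export
coef_summary <- function(df, digits = 3) {
  num <- df[vapply(df, is.numeric, TRUE)]
  do.call(rbind, lapply(names(num), function(v) {
    x <- num[[v]]
    x <- x[!is.na(x)]
    r <- round(x, digits)
    md <- as.numeric(names(which.max(table(r))))
    q <- stats::quantile(x, c(0.025, 0.975, 0.125, 0.875), names = FALSE)
    data.frame(coefficient = v, mean = mean(x), sd = stats::sd(x),
               median = stats::median(x), mode = md,
               ci95_lo = q[1], ci95_hi = q[2], ci75_lo = q[3], ci75_hi = q[4],
               stringsAsFactors = FALSE)
  }))
}
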
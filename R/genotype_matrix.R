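#' Construct a genotype matrix
#'
#' The central genotype container: an integer matrix of minor-allele dosages
#' (individuals in rows, SNPs in columns, `NA` for missing calls) tied to a
#' marker map. Genotypes are coded as the count of the within-dataset minor
#' allele (0, 1, 2); ties in allele frequency are broken by allele-symbol
#' order so the coding is reproducible.
#'
#' @param calls Integer matrix, samples x SNPs, values in \{0, 1, 2, NA\}.
#' @param map Data frame with columns `chrom` (autosome label), `snp_id`,
#'   `pos_bp` (1-based physical position), `a1`, `a2` (allele symbols; `a1`
#'   is the counted allele).
#' @param samples Character vector of individual ids, one per row of `calls`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, map, samples = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(samples)) samples <- paste0("ind", seq_len(nrow(calls)))
  samples <- as.character(samples)
  stopifnot(
    nrow(calls) == length(samples),
    ncol(calls) == nrow(map),
    all(c("chrom", "snp_id", "pos_bp", "a1", "a2") %in% names(map))
  )
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA")
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  # canonical marker order: by chromosome then position
  ord <- order(map$chrom, map$pos_bp)
  map <- map[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  rownames(map) <- NULL
  for (ch in split(map$pos_bp, map$chrom))
    if (is.unsorted(ch, strictly = TRUE))
      stop("marker positions must be strictly increasing within chromosome")
  dimnames(calls) <- list(samples, map$snp_id)
  structure(list(calls = calls, map = map, samples = samples),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs on %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$map$chrom))))
  cat(sprintf("  missing rate: %.4f\n", mean(is.na(x$calls))))
  invisible(x)
}

#' Number of samples / markers
#' @param gm A `genotype_matrix`.
#' @return Integer count.
#' @export
n_samples <- function(gm) nrow(gm$calls)

#' @rdname n_samples
#' @export
n_markers <- function(gm) ncol(gm$calls)

#' Sample (minor) allele frequencies
#'
#' Frequency of the counted allele at each SNP, from non-missing calls.
#'
#' @param gm A `genotype_matrix`.
#' @return Numeric vector, one frequency per SNP.
#' @export
allele_freq <- function(gm) {
  colMeans(gm$calls, na.rm = TRUE) / 2
}

#' Subset a genotype matrix
#'
#' @param gm A `genotype_matrix`.
#' @param samples Indices or ids of individuals to keep.
#' @param markers Indices or logical vector of SNPs to keep.
#' @return A `genotype_matrix`.
#' @export
subset_gm <- function(gm, samples = NULL, markers = NULL) {
  calls <- gm$calls
  map <- gm$map
  ids <- gm$samples
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, ids)
    calls <- calls[samples, , drop = FALSE]
    ids <- ids[samples]
  }
  if (!is.null(markers)) {
    calls <- calls[, markers, drop = FALSE]
    map <- map[markers, , drop = FALSE]
  }
  genotype_matrix(calls, map, ids)
}

# Recode calls so the counted allele is the dataset minor allele.
# Ties (freq exactly 0.5) keep the allele that sorts first as a1.
recode_minor <- function(calls, map) {
  p <- colMeans(calls, na.rm = TRUE) / 2
  flip <- p > 0.5 | (p == 0.5 & map$a1 > map$a2)
  flip[is.na(flip)] <- FALSE
  if (any(flip)) {
    calls[, flip] <- 2L - calls[, flip]
    tmp <- map$a1[flip]
    map$a1[flip] <- map$a2[flip]
    map$a2[flip] <- tmp
  }
  list(calls = calls, map = map)
}
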
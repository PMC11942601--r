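#' Read PLINK binary genotypes (.bed/.bim/.fam)
#'
#' Reads the PLINK v1.00 SNP-major binary layout. Two-bit codes are mapped to
#' minor-allele dosages: the counted allele (`a1`) is re-assigned to the
#' dataset minor allele after loading, so dosages always count the rarer
#' allele. Markers are returned sorted by (chromosome, position); missing
#' calls are preserved as `NA`.
#'
#' @param bed_path Path to the `.bed` file (or a bare prefix; `.bed`, `.bim`,
#'   `.fam` are appended when `bim_path`/`fam_path` are missing).
#' @param bim_path,fam_path Paths to the marker map and sample files.
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(bed_path, bim_path = NULL, fam_path = NULL) {
  if (is.null(bim_path) && !grepl("\\.bed$", bed_path)) {
    bim_path <- paste0(bed_path, ".bim")
    fam_path <- paste0(bed_path, ".fam")
    bed_path <- paste0(bed_path, ".bed")
  }
  if (is.null(bim_path)) bim_path <- sub("\\.bed$", ".bim", bed_path)
  if (is.null(fam_path)) fam_path <- sub("\\.bed$", ".fam", bed_path)
  stopifnot(file.exists(bed_path), file.exists(bim_path), file.exists(fam_path))

  bim <- utils::read.table(bim_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos_bp", "a1", "a2"))
  fam <- utils::read.table(fam_path, header = FALSE, stringsAsFactors = FALSE)
  n_ind <- nrow(fam)
  n_snp <- nrow(bim)

  raw <- readBin(bed_path, "raw", n = file.info(bed_path)$size)
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (magic bytes absent): ", bed_path)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed (v1.00) is supported")
  bps <- ceiling(n_ind / 4)                 # bytes per SNP
  if (length(raw) - 3L != bps * n_snp)
    stop(sprintf(".bed payload (%d bytes) inconsistent with %d samples x %d SNPs",
                 length(raw) - 3L, n_ind, n_snp))

  body <- raw[-(1:3)]
  # unpack 2-bit fields, sample-fastest within each SNP
  bits <- matrix(as.integer(rawToBits(body)), nrow = 8L)
  two_bit <- bits[seq(1L, 8L, 2L), , drop = FALSE] +
    2L * bits[seq(2L, 8L, 2L), , drop = FALSE]
  codes <- matrix(as.integer(two_bit), nrow = 4L * bps)[seq_len(n_ind), , drop = FALSE]
  # 00 hom a1 -> 2 copies of a1; 01 missing; 10 het; 11 hom a2
  calls <- matrix(NA_integer_, n_ind, n_snp)
  calls[codes == 0L] <- 2L
  calls[codes == 2L] <- 1L
  calls[codes == 3L] <- 0L

  map <- data.frame(chrom = bim$chrom, snp_id = bim$snp_id, pos_bp = bim$pos_bp,
                    a1 = as.character(bim$a1), a2 = as.character(bim$a2),
                    stringsAsFactors = FALSE)
  rc <- recode_minor(calls, map)
  genotype_matrix(rc$calls, rc$map, samples = as.character(fam[[2]]))
}

#' Write PLINK binary genotypes
#'
#' Inverse of [read_plink()]: dosage 2 is written as homozygous `a1`,
#' 0 as homozygous `a2`, `NA` as the missing code.
#'
#' @param gm A [genotype_matrix()].
#' @param prefix Output path prefix; `.bed`, `.bim`, `.fam` are appended.
#' @return The prefix, invisibly.
#' @export
write_plink <- function(gm, prefix) {
  calls <- gm$calls
  map <- gm$map
  n_ind <- nrow(calls)
  n_snp <- ncol(calls)

  codes <- matrix(1L, n_ind, n_snp)         # 01 = missing
  codes[!is.na(calls) & calls == 2L] <- 0L
  codes[!is.na(calls) & calls == 1L] <- 2L
  codes[!is.na(calls) & calls == 0L] <- 3L

  bps <- ceiling(n_ind / 4)
  padded <- matrix(0L, 4L * bps, n_snp)
  padded[seq_len(n_ind), ] <- codes
  lo <- padded %% 2L
  hi <- padded %/% 2L
  bits <- matrix(0L, 8L, bps * n_snp)
  bits[seq(1L, 8L, 2L), ] <- matrix(lo, nrow = 4L)
  bits[seq(2L, 8L, 2L), ] <- matrix(hi, nrow = 4L)
  bytes <- packBits(as.raw(bits), "raw")

  writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), bytes), paste0(prefix, ".bed"))
  utils::write.table(
    data.frame(map$chrom, map$snp_id, 0, map$pos_bp, map$a1, map$a2),
    paste0(prefix, ".bim"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(gm$samples, gm$samples, 0, 0, 0, -9),
    paste0(prefix, ".fam"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read PLINK text genotypes (.ped/.map)
#'
#' @param ped_path,map_path Paths to the `.ped` and `.map` files.
#' @return A [genotype_matrix()].
#' @export
read_ped_map <- function(ped_path, map_path) {
  mp <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "snp_id", "cm", "pos_bp"))
  ped <- utils::read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  n_snp <- nrow(mp)
  if (ncol(ped) != 6L + 2L * n_snp)
    stop(sprintf(".ped has %d columns; expected %d for %d SNPs",
                 ncol(ped), 6L + 2L * n_snp, n_snp))
  al1 <- as.matrix(ped[, 6L + 2L * seq_len(n_snp) - 1L, drop = FALSE])
  al2 <- as.matrix(ped[, 6L + 2L * seq_len(n_snp), drop = FALSE])

  calls <- matrix(NA_integer_, nrow(ped), n_snp)
  a1 <- a2 <- character(n_snp)
  for (j in seq_len(n_snp)) {
    obs <- c(al1[, j], al2[, j])
    obs <- sort(unique(obs[obs != "0"]))
    if (length(obs) > 2L)
      stop("more than two alleles at SNP ", mp$snp_id[j])
    a1[j] <- if (length(obs)) obs[1] else "A"
    a2[j] <- if (length(obs) == 2L) obs[2] else a1[j]
    ok <- al1[, j] != "0" & al2[, j] != "0"
    calls[ok, j] <- (al1[ok, j] == a1[j]) + (al2[ok, j] == a1[j])
  }
  map <- data.frame(chrom = mp$chrom, snp_id = mp$snp_id, pos_bp = mp$pos_bp,
                    a1 = a1, a2 = a2, stringsAsFactors = FALSE)
  rc <- recode_minor(calls, map)
  genotype_matrix(rc$calls, rc$map, samples = ped[[2]])
}

#' Write PLINK text genotypes (.ped/.map)
#'
#' @param gm A [genotype_matrix()].
#' @param prefix Output path prefix; `.ped` and `.map` are appended.
#' @return The prefix, invisibly.
#' @export
write_ped_map <- function(gm, prefix) {
  calls <- gm$calls
  map <- gm$map
  n_snp <- ncol(calls)
  out <- matrix("0", nrow(calls), 2L * n_snp)
  for (j in seq_len(n_snp)) {
    g <- calls[, j]
    out[, 2L * j - 1L] <- ifelse(is.na(g), "0", ifelse(g >= 1L, map$a1[j], map$a2[j]))
    out[, 2L * j] <- ifelse(is.na(g), "0", ifelse(g == 2L, map$a1[j], map$a2[j]))
  }
  ped <- cbind(gm$samples, gm$samples, "0", "0", "0", "-9", out)
  utils::write.table(ped, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(map$chrom, map$snp_id, 0, map$pos_bp),
                     paste0(prefix, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a pedigree table
#'
#' Four-column delimited text: individual id, sire id, dam id, birth year.
#' `0`, `NA` or empty fields mark unknown parents.
#'
#' @param path Path to the pedigree file.
#' @param header Does the file carry a header row?
#' @return A [pedigree_table()].
#' @export
read_pedigree <- function(path, header = TRUE) {
  df <- utils::read.table(path, header = header, sep = "", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  names(df)[1:3] <- c("id", "sire", "dam")
  if (ncol(df) >= 4) names(df)[4] <- "birth_year"
  pedigree_table(df)
}
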
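#' Per-SNP ROH incidence
#'
#' For every post-QC SNP, the count (and fraction) of individuals whose runs
#' of homozygosity cover its position. A SNP is counted when it lies within
#' `[start_bp, end_bp]` of a segment; segments of one individual never
#' overlap, so each individual contributes at most once per SNP.
#'
#' @param segments A `roh_segments` data frame.
#' @param map Marker map (`chrom`, `snp_id`, `pos_bp`).
#' @param n_indiv Number of individuals the segments were detected in.
#' @return Data frame of class `incidence_track` with `chrom`, `pos_bp`,
#'   `snp_id`, `count`, `fraction`; attribute `n_indiv`.
#' @export
roh_incidence <- function(segments, map, n_indiv) {
  stopifnot(n_indiv >= 1)
  count <- integer(nrow(map))
  for (ch in unique(map$chrom)) {
    mi <- which(map$chrom == ch)
    pos <- map$pos_bp[mi]
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    if (!nrow(seg)) next
    # difference track: +1 at first covered SNP, -1 after the last
    d <- integer(length(pos) + 1L)
    i1 <- findInterval(seg$start_bp - 1, pos) + 1L
    i2 <- findInterval(seg$end_bp, pos)
    ok <- i1 <= i2 & i1 <= length(pos)
    for (k in which(ok)) {
      d[i1[k]] <- d[i1[k]] + 1L
      d[i2[k] + 1L] <- d[i2[k] + 1L] - 1L
    }
    count[mi] <- cumsum(d[-length(d)])
  }
  out <- data.frame(chrom = map$chrom, pos_bp = map$pos_bp,
                    snp_id = map$snp_id, count = count,
                    fraction = count / n_indiv, stringsAsFactors = FALSE)
  attr(out, "n_indiv") <- n_indiv
  class(out) <- c("incidence_track", "data.frame")
  out
}

# maximal runs of TRUE per chromosome -> region rows
qualifying_runs <- function(track, qualify, kind, max_bridge = 0L) {
  out <- list()
  for (ch in unique(track$chrom)) {
    mi <- which(track$chrom == ch)
    q <- qualify[mi]
    if (max_bridge > 0L) {
      # merge qualifying runs separated by short non-qualifying stretches
      r <- rle(q)
      inner <- which(!r$values & r$lengths <= max_bridge)
      inner <- inner[inner > 1L & inner < length(r$values)]
      r$values[inner] <- TRUE
      q <- inverse.rle(r)
    }
    r <- rle(q)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      idx <- mi[starts[k]:ends[k]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_bp = track$pos_bp[idx[1]],
        end_bp = track$pos_bp[idx[length(idx)]],
        n_snps = length(idx), kind = kind, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = integer(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_snps = integer(0),
                      kind = character(0)))
  do.call(rbind, out)
}

#' Consensus ROH regions
#'
#' Maximal runs of consecutive SNPs whose ROH incidence fraction reaches the
#' sharing threshold; region bounds sit at the first and last qualifying SNP.
#'
#' @param track An `incidence_track` from [roh_incidence()].
#' @param threshold Sharing fraction in (0, 1\].
#' @return Data frame with `chrom`, `start_bp`, `end_bp`, `n_snps`, `kind`
#'   (possibly zero rows).
#' @export
consensus_roh <- function(track, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  qualifying_runs(track, track$fraction >= threshold,
                  sprintf("consensus_%g", threshold))
}

#' ROH islands above an incidence percentile
#'
#' A SNP qualifies when its incidence count strictly exceeds the genome-wide
#' percentile of the per-SNP incidence distribution (linear-interpolation
#' quantile); maximal qualifying runs are emitted, optionally bridging runs
#' separated by at most `max_bridge` non-qualifying SNPs.
#'
#' @param track An `incidence_track`.
#' @param percentile Percentile in (0, 100); 99 by convention.
#' @param max_bridge Merge runs separated by at most this many SNPs
#'   (0 = no merging).
#' @return Data frame of regions as in [consensus_roh()]; empty (with a
#'   warning) when the incidence distribution is degenerate.
#' @export
percentile_islands <- function(track, percentile = 99, max_bridge = 0L) {
  stopifnot(percentile > 0, percentile < 100)
  q <- stats::quantile(track$count, percentile / 100, names = FALSE, type = 7)
  qualify <- track$count > q
  if (!any(qualify)) {
    if (stats::var(track$count) == 0)
      warning("degenerate incidence distribution; no island exceeds the percentile")
    return(qualifying_runs(track, qualify, "percentile_island"))
  }
  qualifying_runs(track, qualify, "percentile_island", max_bridge = max_bridge)
}

#' Annotate regions with genes from a local annotation file
#'
#' Joins regions against a user-supplied GFF3 or BED gene annotation read
#' with `rtracklayer`; each gene id is counted once per region it overlaps.
#' With no file (or when `rtracklayer` is unavailable) the regions are
#' returned unannotated with a message.
#'
#' @param regions Region data frame ([consensus_roh()] / [percentile_islands()]).
#' @param annotation_file Path to a GFF3/BED file, or `NULL`.
#' @param feature_type GFF3 feature type to keep (default `"gene"`); ignored
#'   for BED input or when absent from the file.
#' @return `regions` with `n_genes` and a comma-separated `genes` column.
#' @export
annotate_regions <- function(regions, annotation_file = NULL,
                             feature_type = "gene") {
  regions$n_genes <- rep(NA_integer_, nrow(regions))
  regions$genes <- rep(NA_character_, nrow(regions))
  if (is.null(annotation_file) || !file.exists(annotation_file %||% "")) {
    message("no annotation file; regions returned unannotated")
    return(regions)
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
      !requireNamespace("GenomicRanges", quietly = TRUE)) {
    message("rtracklayer/GenomicRanges not installed; regions returned unannotated")
    return(regions)
  }
  ann <- rtracklayer::import(annotation_file)
  md <- S4Vectors::mcols(ann)
  if ("type" %in% names(md) && any(md$type == feature_type))
    ann <- ann[md$type == feature_type]
  md <- S4Vectors::mcols(ann)
  ids <- if ("gene_id" %in% names(md)) md$gene_id
         else if ("ID" %in% names(md)) md$ID
         else if ("Name" %in% names(md)) md$Name
         else if ("name" %in% names(md)) md$name
         else as.character(seq_along(ann))
  for (i in seq_len(nrow(regions))) {
    reg <- GenomicRanges::GRanges(
      as.character(regions$chrom[i]),
      IRanges::IRanges(regions$start_bp[i], regions$end_bp[i]))
    hit <- unique(ids[S4Vectors::queryHits(
      GenomicRanges::findOverlaps(ann, reg))])
    regions$n_genes[i] <- length(hit)
    regions$genes[i] <- paste(hit, collapse = ",")
  }
  regions
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export regions
#'
#' TSV mirrors the island-table layout (chromosome, start, end, SNP count,
#' gene count); BED is 0-based half-open.
#'
#' @param regions Region data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_regions_tsv <- function(regions, path) {
  utils::write.table(regions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_regions_tsv
#' @export
write_regions_bed <- function(regions, path) {
  utils::write.table(
    data.frame(regions$chrom, regions$start_bp - 1, regions$end_bp,
               regions$kind),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
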
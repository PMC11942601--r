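# Fixture builders and independent oracles used across the suite.

# genotype_matrix from a calls matrix on a single chromosome
make_gm <- function(calls, pos = NULL, chrom = 1L, ids = NULL) {
  m <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(m) * 10000
  map <- data.frame(chrom = rep(chrom, m),
                    snp_id = paste0("s", chrom, "_", seq_len(m)),
                    pos_bp = pos, a1 = "B", a2 = "A",
                    stringsAsFactors = FALSE)
  if (is.null(ids)) ids <- paste0("i", seq_len(nrow(calls)))
  genotype_matrix(calls, map, ids)
}

# random single-individual genotype vector biased towards homozygosity
random_roh_genotypes <- function(n_snps, p_het = 0.08, p_miss = 0.03) {
  g <- sample(c(0L, 2L), n_snps, replace = TRUE)
  g[runif(n_snps) < p_het] <- 1L
  g[runif(n_snps) < p_miss] <- NA_integer_
  g
}

# Exhaustive reference ROH scanner: explicit loops over every window and
# every candidate run, written independently of the package's vectorized
# detector.
brute_force_roh <- function(g, pos, params) {
  L <- length(g)
  w <- params$window_snps
  elig <- rep(FALSE, L)
  if (L >= w) {
    nw <- L - w + 1
    verdict <- logical(nw)
    for (j in seq_len(nw)) {
      win <- g[j:(j + w - 1)]
      verdict[j] <- sum(win == 1L, na.rm = TRUE) <= params$max_het_in_window &&
        sum(is.na(win)) <= params$max_missing_in_window
    }
    for (i in seq_len(L)) {
      js <- max(1, i - w + 1):min(nw, i)
      elig[i] <- mean(verdict[js]) >= params$window_hit_fraction
    }
  }
  segs <- list()
  i <- 1
  while (i <= L) {
    if (!elig[i]) { i <- i + 1; next }
    j <- i
    while (j < L && elig[j + 1]) j <- j + 1
    # split the run [i, j] at large gaps
    piece_start <- i
    for (k in i:j) {
      end_piece <- k == j ||
        (pos[k + 1] - pos[k] > params$max_gap_kb * 1000)
      if (end_piece) {
        n <- k - piece_start + 1
        len <- pos[k] - pos[piece_start] + 1
        if (n >= params$min_snps_in_roh &&
            len >= params$min_length_kb * 1000 &&
            len / 1000 / n <= params$min_density_kb_per_snp)
          segs[[length(segs) + 1]] <- c(pos[piece_start], pos[k], n)
        piece_start <- k + 1
      }
    }
    i <- j + 1
  }
  if (!length(segs))
    return(data.frame(start_bp = numeric(0), end_bp = numeric(0),
                      n_snps = integer(0)))
  m <- do.call(rbind, segs)
  data.frame(start_bp = m[, 1], end_bp = m[, 2], n_snps = as.integer(m[, 3]))
}

# Wright's path-counting inbreeding oracle (exponential; small pedigrees
# only). F_X = sum over common ancestors A and over pairs of parent->A
# paths sharing only A of (1/2)^(n1+n2+1) (1 + F_A).
wright_path_f <- function(ped) {
  sire <- setNames(ped$sire, ped$id)
  dam <- setNames(ped$dam, ped$id)
  paths_up <- function(id) {
    # all ancestor paths as vectors starting at id
    out <- list(id)
    for (p in c(sire[[id]], dam[[id]])) {
      if (is.na(p)) next
      for (pp in paths_up(p)) out[[length(out) + 1]] <- c(id, pp)
    }
    out
  }
  f <- setNames(numeric(nrow(ped)), ped$id)
  for (id in ped$id) {                 # ped is topologically ordered
    s <- sire[[id]]; d <- dam[[id]]
    if (is.na(s) || is.na(d)) next
    ps <- paths_up(s)
    pd <- paths_up(d)
    val <- 0
    for (a in ps) for (b in pd) {
      anc <- a[length(a)]
      if (b[length(b)] != anc) next
      shared <- intersect(a, b)
      if (length(shared) != 1 || shared != anc) next
      val <- val + 0.5^(length(a) + length(b) - 1) * (1 + f[[anc]])
    }
    f[[id]] <- val
  }
  f
}

# random multi-generation pedigree with known parents drawn from the
# previous generation
random_pedigree <- function(n_gen = 6, per_gen = 4, n_founders = 4) {
  ids <- paste0("f", seq_len(n_founders))
  df <- data.frame(id = ids, sire = NA_character_, dam = NA_character_,
                   stringsAsFactors = FALSE)
  prev <- ids
  for (g in seq_len(n_gen)) {
    cur <- character(per_gen)
    for (k in seq_len(per_gen)) {
      id <- paste0("g", g, "_", k)
      par <- sample(prev, 2)           # distinct parents
      df <- rbind(df, data.frame(id = id, sire = par[1], dam = par[2],
                                 stringsAsFactors = FALSE))
      cur[k] <- id
    }
    prev <- cur
  }
  pedigree_table(df)
}

# quadratic per-SNP ROH membership scan (incidence oracle)
brute_force_incidence <- function(segments, map, n_indiv) {
  count <- integer(nrow(map))
  for (i in seq_len(nrow(map))) {
    covered <- unique(segments$iid[
      segments$chrom == map$chrom[i] &
        segments$start_bp <= map$pos_bp[i] &
        segments$end_bp >= map$pos_bp[i]])
    count[i] <- length(covered)
  }
  count
}

# small GFF3 gene annotation written to a temp file
write_test_gff <- function(genes, path = tempfile(fileext = ".gff3")) {
  lines <- c("##gff-version 3",
             sprintf("%s\ttest\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                     genes$chrom, genes$start, genes$end, genes$id))
  writeLines(lines, path)
  path
}
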
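#' Simulation configuration
#'
#' Study-shaped defaults: a diploid autosomal genome of 10 chromosomes with
#' 2,000 SNPs each at ~30 kb mean spacing (a desk-scale rendering of a ~65k
#' equine array over 31 autosomes), 50 founders plus 5 generations of 30
#' offspring (200 individuals in total), founder allele frequencies from a
#' truncated Beta(0.5, 0.5) spectrum giving mean SNP heterozygosity near
#' 0.27, and a uniform 1 cM/Mb recombination map so that run length dates
#' inbreeding at g = 100/(2 L) generations.
#'
#' @param n_chrom Number of autosomes.
#' @param snps_per_chrom SNPs per autosome.
#' @param spacing_bp Mean inter-SNP spacing (bp).
#' @param spacing_jitter_bp Half-width of the uniform jitter on spacings.
#' @param founder_count Number of unrelated founders.
#' @param n_generations Generations bred after the founders.
#' @param offspring_per_gen Offspring per generation (`random` scheme).
#' @param mating `"random"`, `"full_sib_loops"` or `"wright_fisher"`.
#' @param wf_n Constant population size for the `wright_fisher` scheme.
#' @param offspring_per_family Full sibs bred per family per generation
#'   (`full_sib_loops` scheme).
#' @param missing_rate Genotype missingness in \[0, 1).
#' @param maf_beta Shape parameters of the founder-frequency Beta spectrum.
#' @param maf_range Truncation bounds on founder frequencies.
#' @param cm_per_mb Recombination rate (centimorgan per megabase).
#' @param track_ibd Record founder-allele labels and emit identity-by-
#'   descent truth? (Disable for long Wright-Fisher runs where only the LD
#'   structure matters.)
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 10L, snps_per_chrom = 2000L,
                       spacing_bp = 30000, spacing_jitter_bp = 10000,
                       founder_count = 50L, n_generations = 5L,
                       offspring_per_gen = 30L,
                       mating = c("random", "full_sib_loops", "wright_fisher"),
                       wf_n = 100L, offspring_per_family = 2L,
                       missing_rate = 0, maf_beta = c(0.5, 0.5),
                       maf_range = c(0.01, 0.99), cm_per_mb = 1,
                       track_ibd = TRUE, seed = 1L) {
  mating <- match.arg(mating)
  stopifnot(n_chrom >= 1, snps_per_chrom >= 2, founder_count >= 2,
            missing_rate >= 0, missing_rate < 1, cm_per_mb > 0)
  if (mating == "full_sib_loops" && (founder_count < 2 || offspring_per_family < 2))
    stop("full_sib_loops needs at least one founder pair and two offspring per family")
  structure(as.list(environment()), class = "sim_config")
}

# one recombinant gamete from haplotype rows h1/h2 (+ labels l1/l2)
meiosis <- function(h1, h2, l1, l2, pos, chrom_len_bp, morgan) {
  k <- stats::rpois(1L, morgan)
  cur <- sample.int(2L, 1L) - 1L              # 0 -> h1 first
  if (k == 0L) {
    if (cur == 0L) return(list(a = h1, l = l1))
    return(list(a = h2, l = l2))
  }
  xo <- sort(stats::runif(k, 0, chrom_len_bp))
  phase <- (cur + findInterval(pos, xo)) %% 2L
  a <- h1; l <- l1
  sw <- phase == 1L
  a[sw] <- h2[sw]
  if (!is.null(l1)) l[sw] <- l2[sw]
  list(a = a, l = l)
}

#' Simulate a pedigree with gene-dropped genotypes and known IBD truth
#'
#' Founder haplotypes are drawn from the configured frequency spectrum and
#' uniquely labeled; offspring haplotypes are formed by Haldane-model
#' recombination (Poisson crossovers on the configured map) over the
#' labeled founder chromosomes, so autozygous tracts (both labels equal)
#' are known exactly at marker resolution. Genotypes are emitted as a
#' [genotype_matrix()] in minor-allele dosage coding, together with the
#' pedigree and the per-individual truth.
#'
#' Mating schemes: `random` mates random male x female pairs from the
#' previous generation; `full_sib_loops` breeds full-sib pairs within
#' founder families so inbreeding loops accumulate (offspring of the first
#' sib mating have expected F = 0.25); `wright_fisher` evolves a constant
#' population of `wf_n` monoecious individuals with random parent sampling
#' each generation and returns the final generation.
#'
#' @param cfg A [sim_config()].
#' @return A list with `gm`, `ped` (a [pedigree_table()]) and `truth`
#'   (per-individual `f_true`, autozygous `tracts`, founder frequencies and
#'   the covered genome length).
#' @export
simulate_population <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  m <- cfg$n_chrom * cfg$snps_per_chrom
  chrom <- rep(seq_len(cfg$n_chrom), each = cfg$snps_per_chrom)
  spac <- pmax(1, round(stats::runif(m, cfg$spacing_bp - cfg$spacing_jitter_bp,
                                     cfg$spacing_bp + cfg$spacing_jitter_bp)))
  pos <- as.vector(vapply(split(spac, chrom), cumsum,
                          numeric(cfg$snps_per_chrom)))
  map <- data.frame(chrom = chrom, snp_id = sprintf("snp%d_%d", chrom,
                                                    sequence(rep(cfg$snps_per_chrom, cfg$n_chrom))),
                    pos_bp = pos, a1 = "B", a2 = "A", stringsAsFactors = FALSE)
  p <- stats::rbeta(m, cfg$maf_beta[1], cfg$maf_beta[2])
  p <- pmin(pmax(p, cfg$maf_range[1]), cfg$maf_range[2])
  chrom_idx <- split(seq_len(m), chrom)
  chrom_len <- vapply(chrom_idx, function(i) max(pos[i]) + cfg$spacing_bp,
                      numeric(1))
  morgan <- chrom_len * cfg$cm_per_mb / 1e8

  if (cfg$mating == "wright_fisher")
    return(simulate_wf(cfg, map, p, chrom_idx, chrom_len, morgan))

  nf <- cfg$founder_count
  n_total <- if (cfg$mating == "random") {
    nf + cfg$n_generations * cfg$offspring_per_gen
  } else {
    nf + cfg$n_generations * (nf %/% 2L) * cfg$offspring_per_family
  }
  H1 <- matrix(0L, n_total, m); H2 <- matrix(0L, n_total, m)
  track <- cfg$track_ibd
  L1 <- if (track) matrix(0L, n_total, m) else NULL
  L2 <- if (track) matrix(0L, n_total, m) else NULL
  sire <- dam <- rep(NA_integer_, n_total)
  gen <- integer(n_total)
  sex <- integer(n_total)                      # 1 male, 2 female

  for (i in seq_len(nf)) {
    H1[i, ] <- stats::rbinom(m, 1L, p)
    H2[i, ] <- stats::rbinom(m, 1L, p)
    if (track) { L1[i, ] <- 2L * i - 1L; L2[i, ] <- 2L * i }
    sex[i] <- 1L + (i %% 2L)
  }

  make_child <- function(row, si, di) {
    for (ch in seq_along(chrom_idx)) {
      ci <- chrom_idx[[ch]]
      g1 <- meiosis(H1[si, ci], H2[si, ci],
                    if (track) L1[si, ci], if (track) L2[si, ci],
                    pos[ci] - pos[ci][1], chrom_len[ch], morgan[ch])
      g2 <- meiosis(H1[di, ci], H2[di, ci],
                    if (track) L1[di, ci], if (track) L2[di, ci],
                    pos[ci] - pos[ci][1], chrom_len[ch], morgan[ch])
      H1[row, ci] <<- g1$a; H2[row, ci] <<- g2$a
      if (track) { L1[row, ci] <<- g1$l; L2[row, ci] <<- g2$l }
    }
    sire[row] <<- si; dam[row] <<- di
  }

  row <- nf
  if (cfg$mating == "random") {
    prev <- seq_len(nf)
    for (g in seq_len(cfg$n_generations)) {
      males <- prev[sex[prev] == 1L]; females <- prev[sex[prev] == 2L]
      if (!length(males) || !length(females))
        stop("random mating infeasible: a generation lacks one sex")
      newg <- integer(cfg$offspring_per_gen)
      for (k in seq_len(cfg$offspring_per_gen)) {
        row <- row + 1L
        make_child(row, sample(males, 1L), sample(females, 1L))
        gen[row] <- g; sex[row] <- 1L + (row %% 2L)
        newg[k] <- row
      }
      prev <- newg
    }
  } else {                                     # full_sib_loops
    fam_s <- seq(1L, nf - 1L, by = 2L)
    fam_d <- fam_s + 1L
    for (g in seq_len(cfg$n_generations)) {
      ns <- nd <- integer(length(fam_s))
      for (fam in seq_along(fam_s)) {
        kids <- integer(cfg$offspring_per_family)
        for (k in seq_len(cfg$offspring_per_family)) {
          row <- row + 1L
          make_child(row, fam_s[fam], fam_d[fam])
          gen[row] <- g; sex[row] <- 1L + (k %% 2L)
          kids[k] <- row
        }
        ns[fam] <- kids[sex[kids] == 1L][1]
        nd[fam] <- kids[sex[kids] == 2L][1]
      }
      fam_s <- ns; fam_d <- nd
    }
  }

  ids <- sprintf("ind%04d", seq_len(n_total))
  ped <- pedigree_table(data.frame(
    id = ids, sire = ifelse(is.na(sire), NA, ids[sire]),
    dam = ifelse(is.na(dam), NA, ids[dam]),
    birth_year = 2000L + gen, stringsAsFactors = FALSE))

  calls <- H1 + H2
  storage.mode(calls) <- "integer"
  if (cfg$missing_rate > 0)
    calls[stats::runif(length(calls)) < cfg$missing_rate] <- NA_integer_
  rc <- recode_minor(calls, map)
  gm <- genotype_matrix(rc$calls, rc$map, ids)

  truth <- if (track) ibd_truth(L1, L2, map, ids, chrom_idx) else NULL
  if (!is.null(truth)) truth$founder_freq <- p
  list(gm = gm, ped = ped, truth = truth)
}

# Wright-Fisher branch: constant wf_n monoecious individuals, only the
# current generation's haplotypes are kept in memory
simulate_wf <- function(cfg, map, p, chrom_idx, chrom_len, morgan) {
  N <- cfg$wf_n
  m <- nrow(map)
  H <- matrix(stats::rbinom(2L * N * m, 1L, rep(p, each = 2L * N)), 2L * N, m)
  storage.mode(H) <- "integer"
  ped_rows <- list(data.frame(gen = 0L, id = seq_len(N), sire = NA_integer_,
                              dam = NA_integer_))
  for (g in seq_len(cfg$n_generations)) {
    sires <- sample.int(N, N, replace = TRUE)
    dams <- sample.int(N, N, replace = TRUE)
    Hn <- matrix(0L, 2L * N, m)
    for (ch in seq_along(chrom_idx)) {
      ci <- chrom_idx[[ch]]
      pos0 <- map$pos_bp[ci] - map$pos_bp[ci][1]
      Hn[seq(1L, 2L * N, 2L), ci] <-
        wf_gametes(H[, ci, drop = FALSE], sires, pos0, chrom_len[ch], morgan[ch])
      Hn[seq(2L, 2L * N, 2L), ci] <-
        wf_gametes(H[, ci, drop = FALSE], dams, pos0, chrom_len[ch], morgan[ch])
    }
    H <- Hn
    ped_rows[[g + 1L]] <- data.frame(gen = g, id = seq_len(N), sire = sires,
                                     dam = dams)
  }
  pedr <- do.call(rbind, ped_rows)
  uid <- function(g, i) sprintf("g%03d_%03d", g, i)
  ped <- pedigree_table(data.frame(
    id = uid(pedr$gen, pedr$id),
    sire = ifelse(is.na(pedr$sire), NA, uid(pedr$gen - 1L, pedr$sire)),
    dam = ifelse(is.na(pedr$dam), NA, uid(pedr$gen - 1L, pedr$dam)),
    birth_year = 2000L + pedr$gen, stringsAsFactors = FALSE))

  ids <- uid(cfg$n_generations, seq_len(N))
  calls <- H[seq(1L, 2L * N, 2L), , drop = FALSE] +
           H[seq(2L, 2L * N, 2L), , drop = FALSE]
  storage.mode(calls) <- "integer"
  if (cfg$missing_rate > 0)
    calls[stats::runif(length(calls)) < cfg$missing_rate] <- NA_integer_
  rc <- recode_minor(calls, map)
  list(gm = genotype_matrix(rc$calls, rc$map, ids), ped = ped, truth = NULL)
}

# vectorized meiosis for one chromosome across all gametes of a generation;
# H is the 2N x L haplotype matrix (rows 2i-1, 2i belong to individual i)
wf_gametes <- function(H, parent, pos0, chrom_len_bp, morgan) {
  G <- length(parent)
  L <- ncol(H)
  k <- stats::rpois(G, morgan)
  start <- sample.int(2L, G, replace = TRUE) - 1L
  out <- matrix(0L, G, L)
  plain <- k == 0L
  if (any(plain))
    out[plain, ] <- H[2L * parent[plain] - 1L + start[plain], , drop = FALSE]
  for (g in which(!plain)) {
    xo <- sort.int(stats::runif(k[g], 0, chrom_len_bp), method = "quick")
    phase <- (start[g] + findInterval(pos0, xo)) %% 2L
    v <- H[2L * parent[g] - 1L, ]
    sw <- phase == 1L
    v[sw] <- H[2L * parent[g], ][sw]
    out[g, ] <- v
  }
  out
}

# autozygous tracts and true F from founder-allele labels
ibd_truth <- function(L1, L2, map, ids, chrom_idx) {
  covered <- sum(vapply(chrom_idx, function(i)
    max(map$pos_bp[i]) - min(map$pos_bp[i]), numeric(1)))
  tracts <- list()
  f_true <- numeric(nrow(L1))
  for (s in seq_len(nrow(L1))) {
    tot <- 0
    for (ci in chrom_idx) {
      eq <- L1[s, ci] == L2[s, ci]
      if (!any(eq)) next
      r <- rle(eq)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        i1 <- ci[starts[k]]; i2 <- ci[ends[k]]
        if (i1 == i2) next                       # single-SNP tract: length 0
        tot <- tot + map$pos_bp[i2] - map$pos_bp[i1]
        tracts[[length(tracts) + 1L]] <- data.frame(
          iid = ids[s], chrom = map$chrom[i1], start_bp = map$pos_bp[i1],
          end_bp = map$pos_bp[i2], stringsAsFactors = FALSE)
      }
    }
    f_true[s] <- tot / covered
  }
  tr <- if (length(tracts)) do.call(rbind, tracts) else
    data.frame(iid = character(0), chrom = integer(0),
               start_bp = numeric(0), end_bp = numeric(0))
  tr$length_bp <- if (nrow(tr)) tr$end_bp - tr$start_bp else numeric(0)
  list(f_true = stats::setNames(f_true, ids), tracts = tr,
       covered_bp = covered)
}

#' Plant a shared homozygous region
#'
#' Makes a stated fraction of individuals homozygous for one haplotype (the
#' major allele at every SNP) across a region, producing a consensus run of
#' homozygosity detectable by the islands stage. The shared haplotype is
#' delimited: carriers are set heterozygous at the `boundary_het` markers
#' flanking the region on each side (they hold the shared haplotype against
#' a different background), so the detectable edge of the planted region is
#' pinned to the first/last region SNP up to the window tolerance of the
#' detector.
#'
#' @param gm A [genotype_matrix()].
#' @param chrom,start_bp,end_bp The region to plant.
#' @param share_fraction Fraction of individuals made homozygous, in \[0, 1\].
#' @param boundary_het Number of flanking markers per side forced
#'   heterozygous in carriers; use one more than the detector's per-window
#'   heterozygote allowance for sharp edges.
#' @param min_detectable_kb Warn when the region is shorter than this
#'   (shorter regions cannot surface as runs under the default calibration).
#' @param seed Seed for choosing the carrier individuals.
#' @return The modified `genotype_matrix`, with the carrier ids in
#'   attribute `carriers`.
#' @export
plant_island <- function(gm, chrom, start_bp, end_bp, share_fraction,
                         boundary_het = 2L, min_detectable_kb = 2230,
                         seed = 1L) {
  stopifnot(share_fraction >= 0, share_fraction <= 1, end_bp > start_bp)
  on_chr <- which(gm$map$chrom == chrom)
  snps <- on_chr[gm$map$pos_bp[on_chr] >= start_bp &
                 gm$map$pos_bp[on_chr] <= end_bp]
  if (!length(snps)) stop("region contains no SNP")
  if ((end_bp - start_bp) / 1000 < min_detectable_kb)
    warning("planted region is shorter than the minimum detectable run")
  if (share_fraction == 0) return(gm)
  set.seed(seed)
  n_carrier <- ceiling(share_fraction * n_samples(gm))
  carriers <- sample.int(n_samples(gm), n_carrier)
  gm$calls[carriers, snps] <- 0L               # homozygous major haplotype
  if (boundary_het > 0L) {
    lo <- setdiff(intersect(min(snps) - seq_len(boundary_het), on_chr), snps)
    hi <- setdiff(intersect(max(snps) + seq_len(boundary_het), on_chr), snps)
    gm$calls[carriers, c(lo, hi)] <- 1L
  }
  attr(gm, "carriers") <- gm$samples[carriers]
  gm
}
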
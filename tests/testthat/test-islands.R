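simple_map <- function(m = 50, chrom = 1L, step = 1e5) {
  data.frame(chrom = rep(chrom, m), snp_id = paste0("c", chrom, "_", 1:m),
             pos_bp = (1:m) * step, a1 = "B", a2 = "A",
             stringsAsFactors = FALSE)
}

test_that("incidence counts individuals covering each SNP", {
  map <- simple_map(50)
  seg1 <- data.frame(iid = "a", chrom = 1, start_bp = 10e5, end_bp = 20e5,
                     n_snps = 11L, length_bp = 10e5 + 1)
  tr <- roh_incidence(seg1, map, n_indiv = 10)
  expect_equal(sum(tr$count), 11)
  expect_equal(unique(tr$fraction[tr$count > 0]), 0.1)
  expect_true(all(tr$fraction[map$pos_bp < 10e5] == 0))

  # everyone shares the same segment
  segs <- do.call(rbind, lapply(letters[1:10], function(i)
    transform(seg1, iid = i)))
  tra <- roh_incidence(segs, map, 10)
  expect_equal(unique(tra$fraction[tra$count > 0]), 1.0)
})

test_that("incidence equals the quadratic membership oracle and conserves counts", {
  set.seed(50)
  map <- rbind(simple_map(60, 1L), simple_map(40, 2L))
  segs <- do.call(rbind, lapply(1:12, function(i) {
    ch <- sample(1:2, 1)
    n <- if (ch == 1) 60 else 40
    a <- sort(sample(n, 2))
    data.frame(iid = paste0("i", sample(6, 1)), chrom = ch,
               start_bp = a[1] * 1e5, end_bp = a[2] * 1e5,
               n_snps = a[2] - a[1] + 1L,
               length_bp = (a[2] - a[1]) * 1e5 + 1)
  }))
  # collapse overlapping segments of one individual (invariant requires
  # non-overlap within individual)
  segs <- segs[!duplicated(segs[c("iid", "chrom")]), ]
  tr <- roh_incidence(segs, map, 6)
  expect_equal(tr$count, brute_force_incidence(segs, map, 6))
  expect_equal(sum(tr$count), sum(segs$n_snps))
})

test_that("consensus regions cover exactly the sufficiently shared SNPs", {
  map <- simple_map(50)
  seg <- data.frame(iid = letters[1:10], chrom = 1, start_bp = 10e5,
                    end_bp = 20e5, n_snps = 11L, length_bp = 10e5 + 1)
  tr <- roh_incidence(seg, map, 10)
  full <- consensus_roh(tr, 1.0)
  expect_equal(nrow(full), 1L)
  expect_equal(full$start_bp, 10e5)
  expect_equal(full$end_bp, 20e5)
  expect_equal(full$n_snps, 11L)

  expect_equal(nrow(consensus_roh(tr, 1)), 1L)
  tr$fraction <- tr$fraction * 0.5
  expect_equal(nrow(consensus_roh(tr, 0.9)), 0L)   # above max incidence
})

test_that("lower consensus thresholds cover at least the higher-threshold regions", {
  set.seed(60)
  map <- simple_map(200)
  segs <- do.call(rbind, lapply(1:20, function(i) {
    a <- sort(sample(200, 2))
    data.frame(iid = paste0("i", i), chrom = 1, start_bp = a[1] * 1e5,
               end_bp = a[2] * 1e5, n_snps = diff(a) + 1L,
               length_bp = diff(a) * 1e5 + 1)
  }))
  tr <- roh_incidence(segs, map, 20)
  covered_set <- function(reg) {
    if (!nrow(reg)) return(integer(0))
    unlist(lapply(seq_len(nrow(reg)), function(i)
      which(map$pos_bp >= reg$start_bp[i] & map$pos_bp <= reg$end_bp[i])))
  }
  lo <- covered_set(consensus_roh(tr, 0.2))
  hi <- covered_set(consensus_roh(tr, 0.4))
  expect_true(all(hi %in% lo))
})

test_that("percentile islands are the strict-exceedance set of the 99th percentile", {
  # a spike must cover under 1% of SNPs to clear the 99th percentile
  map <- simple_map(3000)
  count <- rep(2L, 3000)
  count[1000:1020] <- 25L                   # one spike region (0.7% of SNPs)
  tr <- structure(data.frame(chrom = 1, pos_bp = map$pos_bp,
                             snp_id = map$snp_id, count = count,
                             fraction = count / 30),
                  class = c("incidence_track", "data.frame"))
  isl <- percentile_islands(tr, 99)
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$start_bp, map$pos_bp[1000])
  expect_equal(isl$end_bp, map$pos_bp[1020])

  # uniform incidence: nothing strictly exceeds the percentile
  tru <- tr; tru$count <- rep(3L, 3000); tru$fraction <- 0.1
  expect_warning(none <- percentile_islands(tru, 99), "degenerate")
  expect_equal(nrow(none), 0L)

  # sort-based oracle on a randomly scattered skewed track
  set.seed(70)
  trx <- tr
  trx$count <- as.integer(rpois(3000, 2) + ifelse(runif(3000) < 0.005, 20L, 0L))
  q <- quantile(trx$count, 0.99)
  want <- which(trx$count > q)
  expect_gt(length(want), 0)
  got <- percentile_islands(trx, 99)
  got_set <- as.integer(unlist(lapply(seq_len(nrow(got)), function(i)
    which(map$pos_bp >= got$start_bp[i] & map$pos_bp <= got$end_bp[i] &
            trx$count > q))))
  expect_setequal(got_set, want)
})

test_that("bridging merges islands separated by few SNPs", {
  map <- simple_map(100)
  count <- rep(0L, 100)
  count[40:44] <- 10L; count[46:50] <- 10L   # one-SNP gap
  tr <- structure(data.frame(chrom = 1, pos_bp = map$pos_bp,
                             snp_id = map$snp_id, count = count,
                             fraction = count / 10),
                  class = c("incidence_track", "data.frame"))
  expect_equal(nrow(percentile_islands(tr, 90, max_bridge = 0)), 2L)
  merged <- percentile_islands(tr, 90, max_bridge = 1)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$start_bp, map$pos_bp[40])
  expect_equal(merged$end_bp, map$pos_bp[50])
})

test_that("a planted shared region is recovered within one SNP at each edge", {
  sim <- simulate_population(sim_config(
    n_chrom = 3, snps_per_chrom = 1200, spacing_bp = 30000,
    spacing_jitter_bp = 5000, founder_count = 40, n_generations = 2,
    offspring_per_gen = 30, seed = 71))
  gm <- sim$gm
  chr2 <- gm$map[gm$map$chrom == 2, ]
  start <- chr2$pos_bp[200]; end <- chr2$pos_bp[200] + 6.4e6
  gm <- plant_island(gm, 2, start, end, share_fraction = 0.30, seed = 72)
  segs <- detect_roh(gm, roh_params(min_snps_in_roh = 30, min_length_kb = 1500))
  tr <- roh_incidence(segs, gm$map, n_samples(gm))
  cons <- consensus_roh(tr, 0.30)
  cons <- cons[cons$chrom == 2, ]
  hit <- cons[cons$start_bp <= start + 1e6 & cons$end_bp >= end - 1e6, ]
  expect_equal(nrow(hit), 1L)
  # edges within one SNP of the planted bounds
  i1 <- min(which(chr2$pos_bp >= start))
  i2 <- max(which(chr2$pos_bp <= end))
  expect_gte(hit$start_bp, chr2$pos_bp[i1 - 1])
  expect_lte(hit$start_bp, chr2$pos_bp[i1 + 1])
  expect_gte(hit$end_bp, chr2$pos_bp[i2 - 1])
  expect_lte(hit$end_bp, chr2$pos_bp[i2 + 1])
})

test_that("regions gain gene counts from a local annotation file", {
  skip_if_not_installed("rtracklayer")
  regions <- data.frame(chrom = 1, start_bp = 1e6, end_bp = 2e6,
                        n_snps = 10L, kind = "percentile_island")
  gff <- write_test_gff(data.frame(
    chrom = 1, start = c(1.1e6, 1.2e6, 1.9e6, 2.5e6),
    end = c(1.15e6, 1.6e6, 2.1e6, 2.6e6),
    id = c("gene1", "gene2", "gene3", "gene4")))
  ann <- annotate_regions(regions, gff)
  expect_equal(ann$n_genes, 3L)           # gene4 lies outside

  # nested duplicate ids are counted once
  gff2 <- write_test_gff(data.frame(
    chrom = 1, start = c(1.1e6, 1.12e6), end = c(1.5e6, 1.3e6),
    id = c("geneA", "geneA")))
  expect_equal(annotate_regions(regions, gff2)$n_genes, 1L)

  empty <- write_test_gff(data.frame(chrom = integer(0), start = integer(0),
                                     end = integer(0), id = character(0)))
  expect_equal(annotate_regions(regions, empty)$n_genes, 0L)

  expect_message(un <- annotate_regions(regions, NULL), "unannotated")
  expect_true(is.na(un$n_genes))
})
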
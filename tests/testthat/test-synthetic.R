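test_that("identical config and seed give bit-identical simulations", {
  cfg <- sim_config(n_chrom = 2, snps_per_chrom = 300, founder_count = 12,
                    n_generations = 2, offspring_per_gen = 8,
                    missing_rate = 0.02, seed = 99)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$gm$calls, b$gm$calls)
  expect_identical(a$ped, b$ped)
  expect_identical(a$truth$f_true, b$truth$f_true)
})

test_that("offspring genotypes are Mendelian-consistent with their parents", {
  sim <- simulate_population(sim_config(
    n_chrom = 3, snps_per_chrom = 400, founder_count = 16,
    n_generations = 3, offspring_per_gen = 12, seed = 13))
  ped <- sim$ped
  calls <- sim$gm$calls
  rows <- match(ped$id, sim$gm$samples)
  for (i in which(!is.na(ped$sire))) {
    kid <- calls[rows[i], ]
    s <- calls[rows[match(ped$sire[i], ped$id)], ]
    d <- calls[rows[match(ped$dam[i], ped$id)], ]
    # no opposing homozygotes between child and either parent
    expect_equal(sum(kid == 2 & s == 0) + sum(kid == 0 & s == 2), 0)
    expect_equal(sum(kid == 2 & d == 0) + sum(kid == 0 & d == 2), 0)
    # child homozygous requires each parent to carry that allele
    expect_equal(sum(kid == 2 & (s == 0 | d == 0)), 0)
  }
})

test_that("missingness honours the configured rate", {
  base <- sim_config(n_chrom = 2, snps_per_chrom = 500, founder_count = 10,
                     n_generations = 1, offspring_per_gen = 10, seed = 5)
  sim0 <- simulate_population(base)
  expect_equal(mean(is.na(sim0$gm$calls)), 0)

  cfg <- base; cfg$missing_rate <- 0.1
  sim1 <- simulate_population(cfg)
  expect_lt(abs(mean(is.na(sim1$gm$calls)) - 0.1), 0.01)
})

test_that("full-sib loop offspring have true autozygosity near a quarter", {
  sim <- simulate_population(sim_config(
    n_chrom = 6, snps_per_chrom = 600, founder_count = 60,
    n_generations = 2, offspring_per_gen = 2, mating = "full_sib_loops",
    offspring_per_family = 2, seed = 23))
  ped <- sim$ped
  # generation-2 individuals are offspring of full sibs
  gen2 <- ped$id[!is.na(ped$birth_year) & ped$birth_year == 2002]
  expect_gt(length(gen2), 40)
  ft <- sim$truth$f_true[gen2]
  se <- sd(ft) / sqrt(length(ft))
  expect_lt(abs(mean(ft) - 0.25), 3 * se + 0.01)
  # founders carry no autozygosity
  founders <- ped$id[is.na(ped$sire) & is.na(ped$dam)]
  expect_equal(unname(sim$truth$f_true[founders]),
               rep(0, length(founders)))
})

test_that("true F equals tract length over covered genome length", {
  sim <- simulate_population(sim_config(
    n_chrom = 3, snps_per_chrom = 400, founder_count = 10,
    n_generations = 3, offspring_per_gen = 10,
    mating = "full_sib_loops", offspring_per_family = 2, seed = 29))
  tr <- sim$truth$tracts
  by_id <- tapply(tr$length_bp, factor(tr$iid, levels = names(sim$truth$f_true)),
                  sum)
  by_id[is.na(by_id)] <- 0
  expect_equal(as.numeric(by_id) / sim$truth$covered_bp,
               unname(sim$truth$f_true))
  # tracts of one individual never overlap
  for (id in unique(tr$iid)) {
    t1 <- tr[tr$iid == id, ]
    t1 <- t1[order(t1$chrom, t1$start_bp), ]
    same <- t1$chrom[-1] == t1$chrom[-nrow(t1)]
    if (any(same))
      expect_true(all(t1$start_bp[-1][same] > t1$end_bp[-nrow(t1)][same]))
  }
})

test_that("founder heterozygosity lands near the target spectrum", {
  sim <- simulate_population(sim_config(
    n_chrom = 4, snps_per_chrom = 1000, founder_count = 60,
    n_generations = 1, offspring_per_gen = 2, seed = 37))
  s <- summarize_genotypes(sim$gm)
  expect_gt(s$mean_heterozygosity, 0.20)
  expect_lt(s$mean_heterozygosity, 0.35)
})

test_that("Wright-Fisher scheme returns the final generation at constant size", {
  sim <- simulate_population(sim_config(
    mating = "wright_fisher", wf_n = 40, n_chrom = 2, snps_per_chrom = 200,
    n_generations = 5, track_ibd = FALSE, seed = 43))
  expect_equal(n_samples(sim$gm), 40L)
  expect_equal(n_markers(sim$gm), 400L)
  expect_true(all(grepl("^g005_", sim$gm$samples)))
  # every final-generation individual has recorded parents
  last <- sim$ped[sim$ped$id %in% sim$gm$samples, ]
  expect_true(all(!is.na(last$sire) & !is.na(last$dam)))
})

test_that("planting a shared region is a no-op at share zero and total at share one", {
  sim <- simulate_population(sim_config(
    n_chrom = 2, snps_per_chrom = 400, founder_count = 10,
    n_generations = 1, offspring_per_gen = 10, seed = 53))
  gm <- sim$gm
  start <- gm$map$pos_bp[50]; end <- gm$map$pos_bp[250]
  expect_warning(same <- plant_island(gm, 1, start, end, 0,
                                      min_detectable_kb = 1e9), "shorter")
  expect_identical(same$calls, gm$calls)

  all_in <- plant_island(gm, 1, start, end, 1.0, min_detectable_kb = 0)
  reg <- gm$map$chrom == 1 & gm$map$pos_bp >= start & gm$map$pos_bp <= end
  expect_true(all(all_in$calls[, reg] == 0L))
})
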
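test_that("F_ROH is combined segment length over covered autosome length", {
  # one individual whose runs sum to 222.487 Mb on a 2,241.761617 Mb genome
  segs <- data.frame(iid = "a", chrom = 1, start_bp = 1,
                     end_bp = 222.487e6, n_snps = 1000L,
                     length_bp = 222.487e6)
  fr <- f_roh(segs, "a", L_auto = 2241761617)
  expect_equal(round(unname(fr), 3), 0.099)

  expect_equal(unname(f_roh(segs[0, ], c("a", "b"), 1e9)), c(0, 0))

  whole <- data.frame(iid = "a", chrom = 1, start_bp = 1, end_bp = 5e7,
                      n_snps = 100L, length_bp = 5e7)
  expect_equal(unname(f_roh(whole, "a", L_auto = 5e7)), 1.0)
  expect_error(f_roh(whole, "a", 5e7, min_len_mb = -1), "bound")
})

test_that("F_ROH is additive over length classes and monotone in threshold", {
  sim <- simulate_population(sim_config(
    n_chrom = 4, snps_per_chrom = 800, founder_count = 24,
    n_generations = 3, offspring_per_gen = 16, seed = 31))
  p <- roh_params(min_snps_in_roh = 15, min_length_kb = 500)
  segs <- detect_roh(sim$gm, p)
  L <- sim$truth$covered_bp
  ids <- sim$gm$samples
  tab <- f_roh_table(segs, ids, L, thresholds_mb = c(4, 8, 16, 32),
                     class_breaks_mb = c(0.5, 4, 8, 16, 32),
                     ge_pedigree = NULL)
  cls <- grep("^f_roh_class_", names(tab), value = TRUE)
  recomposed <- rowSums(tab[cls]) + tab$f_roh_gt_32
  expect_equal(recomposed, tab$f_roh, tolerance = 1e-12)

  expect_true(all(tab$f_roh_gt_4 >= tab$f_roh_gt_8))
  expect_true(all(tab$f_roh_gt_8 >= tab$f_roh_gt_16))
  expect_true(all(tab$f_roh_gt_16 >= tab$f_roh_gt_32))
  expect_true(all(tab$f_roh >= 0 & tab$f_roh <= 1))
})

test_that("F_ROH tracks true autozygosity on gene-dropped individuals", {
  sim <- simulate_population(sim_config(
    n_chrom = 8, snps_per_chrom = 1000, spacing_bp = 50000,
    spacing_jitter_bp = 10000, founder_count = 30, n_generations = 4,
    offspring_per_gen = 25, mating = "full_sib_loops",
    offspring_per_family = 2, seed = 17))
  # calibrate the run definition from the panel itself, as the workflow does
  s <- summarize_genotypes(sim$gm)
  cal <- min_snp_count(0.05, s$mean_heterozygosity, n_markers(sim$gm),
                       n_samples(sim$gm), s$mean_spacing_bp / 1000)
  p <- roh_params(min_snps_in_roh = cal$min_snps,
                  min_length_kb = cal$min_length_kb)
  segs <- detect_roh(sim$gm, p)
  fr <- f_roh(segs, sim$gm$samples, L_auto = sim$truth$covered_bp)
  ft <- sim$truth$f_true
  expect_gt(sum(ft > 0), 30)
  expect_gt(cor(fr, ft), 0.9)
  expect_lt(abs(mean(fr - ft)), 0.01)
})

test_that("observed homozygosity behaves at its bounds and ties to heterozygosity", {
  gm_hom <- make_gm(matrix(c(0L, 2L, 0L, 2L), 1))
  expect_equal(unname(f_hom(gm_hom)), 1.0)
  gm_half <- make_gm(matrix(c(1L, 1L, 0L, 2L), 1))
  expect_equal(unname(f_hom(gm_half)), 0.5)

  set.seed(12)
  big <- make_gm(matrix(sample(0:2, 60 * 300, replace = TRUE), 60, 300))
  expect_equal(mean(f_hom(big)),
               1 - summarize_genotypes(big)$mean_heterozygosity)

  gm_miss <- make_gm(rbind(c(0L, 2L), c(NA_integer_, NA_integer_)))
  expect_warning(fh <- f_hom(gm_miss), "non-missing")
  expect_true(is.na(fh[2]))
})

test_that("F_IS matches hand computation on a worked five-SNP fixture", {
  calls <- rbind(c(1L, 0L, 2L, 1L, 0L),
                 c(0L, 0L, 2L, 1L, 1L),
                 c(2L, 1L, 1L, 0L, 0L),
                 c(1L, 1L, 2L, 2L, 0L))
  gm <- make_gm(calls)
  p <- colMeans(calls) / 2
  eh <- 2 * p * (1 - p)
  # individual 1: hets at SNPs 1 and 4
  expect_equal(unname(f_is(gm))[1], 1 - 2 / sum(eh))
  # fully homozygous individual scores 1
  gm2 <- make_gm(rbind(calls, c(0L, 0L, 2L, 2L, 0L)))
  expect_equal(unname(f_is(gm2))[5], 1.0)
})

test_that("an individual with expected heterozygosity has F_IS near zero", {
  set.seed(77)
  n <- 400; m <- 1000
  p <- runif(m, 0.1, 0.5)
  calls <- sapply(p, function(q) rbinom(n, 2, q))
  gm <- make_gm(calls)
  fis <- f_is(gm)
  expect_lt(abs(mean(fis)), 0.01)        # HWE sample: no average excess
})

test_that("F-hat estimators hit closed-form values and center at zero under HWE", {
  # all individuals heterozygous everywhere, p = 0.5
  gm <- make_gm(matrix(1L, 5, 8))
  fh <- f_hat(gm)
  expect_equal(fh$f_hat1, rep(-1, 5))    # x = 2p exactly
  expect_equal(fh$f_hat2, rep(-1, 5))    # 1 - 1/(2p(1-p)) at x = 1
  expect_equal(fh$f_hat3, rep(-1, 5))

  set.seed(99)
  n <- 300; m <- 3000
  p <- runif(m, 0.05, 0.5)
  calls <- sapply(p, function(q) rbinom(n, 2, q))
  gmx <- make_gm(calls)
  fhx <- f_hat(gmx)
  expect_lt(abs(mean(fhx$f_hat1)), 0.02)
  expect_lt(abs(mean(fhx$f_hat2)), 0.02)
  expect_lt(abs(mean(fhx$f_hat3)), 0.02)
})

test_that("coefficient summary reports the documented moments", {
  df <- data.frame(iid = letters[1:5], x = c(0.1, 0.2, 0.2, 0.3, 0.4))
  s <- coef_summary(df)
  expect_equal(s$mean, 0.24)
  expect_equal(s$median, 0.2)
  expect_equal(s$mode, 0.2)
})
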
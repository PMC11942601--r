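full_sib_ped <- function() pedigree_table(data.frame(
  id = c("g1", "g2", "s", "d", "x"),
  sire = c(NA, NA, "g1", "g1", "s"),
  dam = c(NA, NA, "g2", "g2", "d")))

test_that("classical inbreeding reproduces textbook pedigrees", {
  expect_equal(unname(meuwissen_luo_f(full_sib_ped())["x"]), 0.25)

  half <- pedigree_table(data.frame(
    id = c("g1", "g2", "g3", "s", "d", "x"),
    sire = c(NA, NA, NA, "g1", "g1", "s"),
    dam = c(NA, NA, NA, "g2", "g3", "d")))
  expect_equal(unname(meuwissen_luo_f(half)["x"]), 0.125)

  expect_equal(unname(meuwissen_luo_f(full_sib_ped())[c("g1", "g2")]), c(0, 0))
})

test_that("tabular inbreeding equals the path-counting oracle on random pedigrees", {
  set.seed(202)
  for (rep in 1:50) {
    ped <- random_pedigree(n_gen = 6, per_gen = 3, n_founders = 3)
    expect_equal(meuwissen_luo_f(ped), wright_path_f(ped), tolerance = 1e-12)
  }
})

test_that("cycles are detected and named", {
  df <- data.frame(id = c("a", "b", "c"), sire = c("c", "a", "b"),
                   dam = c(NA, NA, NA))
  expect_error(pedigree_table(df), "cycle")
})

test_that("equivalent generations measure pedigree depth", {
  ped <- full_sib_ped()
  ge <- equivalent_generations(ped)
  expect_equal(unname(ge["g1"]), 0)          # founder
  expect_equal(unname(ge["s"]), 1)           # both parents known, no deeper
  expect_equal(unname(ge["x"]), 2)           # two complete generations

  # complete 3-generation pedigree: GE = 3
  ids <- c(paste0("f", 1:8), paste0("m", 1:4), paste0("p", 1:2), "x")
  df <- data.frame(
    id = ids,
    sire = c(rep(NA, 8), "f1", "f3", "f5", "f7", "m1", "m3", "p1"),
    dam = c(rep(NA, 8), "f2", "f4", "f6", "f8", "m2", "m4", "p2"))
  expect_equal(unname(equivalent_generations(pedigree_table(df))["x"]), 3)
})

test_that("rate of inbreeding follows the depth-corrected closed form", {
  expect_equal(delta_f_ped(0.25, 2), 0.25)
  expect_equal(delta_f_ped(0, 5), 0)
  expect_equal(delta_f_ped(0, 0.5), 0)       # GE <= 1 reports zero
  expect_equal(round(delta_f_ped(0.099, 15.6691), 4), 0.0071)
  expect_error(delta_f_ped(1.2, 5), "\\[0, 1\\)")
})

test_that("gene drop zeroes founders and classifies first-time autozygosity", {
  gd <- gene_drop_ancestral(full_sib_ped(), mode = "exhaustive")
  f1 <- gd[gd$iid == "g1", ]
  expect_equal(unlist(f1[c("f_a_bal", "f_a_kal", "f_new", "ahc")]),
               c(f_a_bal = 0, f_a_kal = 0, f_new = 0, ahc = 0))
  # offspring of full sibs with non-inbred ancestors: all inbreeding is new
  x <- gd[gd$iid == "x", ]
  expect_equal(x$f_new, 0.25)
  expect_equal(x$f_a_kal, 0)
  expect_equal(x$f_a_bal, 0)
  expect_equal(x$f_ped_drop, 0.25)
})

test_that("Monte-Carlo gene drop agrees with exhaustive enumeration on a looped pedigree", {
  # stacked full-sib loops so ancestral autozygosity occurs (and, by the
  # last generation, repeats, so Ahc strictly exceeds the Ballou coefficient)
  df <- data.frame(
    id = c("a", "b", "c", "d", "e", "f", "g", "h", "i", "j"),
    sire = c(NA, NA, "a", "a", "c", "c", "e", "e", "g", "g"),
    dam = c(NA, NA, "b", "b", "d", "d", "f", "f", "h", "h"))
  ped <- pedigree_table(df)
  ex <- gene_drop_ancestral(ped, mode = "exhaustive")
  R <- 2e4
  mc <- gene_drop_ancestral(ped, rounds = R, seed = 5)
  for (v in c("f_a_bal", "f_a_kal", "f_new", "ahc", "f_ped_drop")) {
    se <- pmax(sqrt(ex[[v]] * pmax(1 - ex[[v]], 0.01) / R), 1e-3)
    expect_true(all(abs(mc[[v]] - ex[[v]]) < 3.5 * se),
                info = paste("coefficient", v))
  }
  # deepest individuals have accumulated (repeated) ancestral autozygosity
  expect_gt(ex[ex$iid == "h", "f_a_bal"], 0)
  expect_gt(ex[ex$iid == "j", "ahc"], ex[ex$iid == "j", "f_a_bal"])
})

test_that("new plus ancestral inbreeding decomposes classical F exactly", {
  set.seed(303)
  for (rep in 1:5) {
    ped <- random_pedigree(n_gen = 3, per_gen = 2, n_founders = 3)
    ex <- gene_drop_ancestral(ped, mode = "exhaustive")
    f <- meuwissen_luo_f(ped)
    expect_equal(ex$f_new + ex$f_a_kal, unname(f[ex$iid]), tolerance = 1e-12)
    expect_equal(ex$f_ped_drop, unname(f[ex$iid]), tolerance = 1e-12)
  }
})

test_that("ancestral coefficients keep their ordering on every individual", {
  set.seed(404)
  for (rep in 1:5) {
    ped <- random_pedigree(n_gen = 5, per_gen = 3, n_founders = 3)
    gd <- gene_drop_ancestral(ped, rounds = 5000, seed = rep,
                              target_se = 0.01)
    expect_true(all(gd$ahc >= gd$f_a_bal - 1e-12))
    expect_true(all(gd$f_a_bal >= gd$f_a_kal - 1e-12))
  }
})

test_that("gene-drop autozygosity converges to the tabular coefficient", {
  ped <- random_pedigree(n_gen = 5, per_gen = 4, n_founders = 4)
  f <- meuwissen_luo_f(ped)
  R <- 1e5
  gd <- gene_drop_ancestral(ped, rounds = R, seed = 8)
  se <- pmax(sqrt(f[gd$iid] * (1 - f[gd$iid]) / R), 5e-4)
  expect_true(all(abs(gd$f_ped_drop - f[gd$iid]) < 3 * se))
})

test_that("results are invariant to individual relabeling", {
  df <- data.frame(
    id = c("a", "b", "c", "d", "e"),
    sire = c(NA, NA, "a", "a", "c"),
    dam = c(NA, NA, "b", "b", "d"))
  relab <- c(a = "Q9", b = "Z2", c = "M1", d = "K7", e = "B4")
  df2 <- data.frame(id = unname(relab[df$id]),
                    sire = unname(relab[df$sire]),
                    dam = unname(relab[df$dam]))
  df2 <- df2[c(3, 5, 1, 2, 4), ]            # shuffle rows too
  g1 <- gene_drop_ancestral(pedigree_table(df), mode = "exhaustive")
  g2 <- gene_drop_ancestral(pedigree_table(df2), mode = "exhaustive")
  for (v in c("f_a_bal", "f_a_kal", "f_new", "ahc"))
    expect_equal(g2[[v]][match(relab[g1$iid], g2$iid)], g1[[v]],
                 tolerance = 1e-12)
  expect_equal(meuwissen_luo_f(pedigree_table(df2))[unname(relab)],
               setNames(meuwissen_luo_f(pedigree_table(df)), relab)[unname(relab)])
})

test_that("single unknown parents act as unique founders", {
  df <- data.frame(id = c("m", "x"), sire = c(NA, "m"), dam = c(NA, NA))
  expect_equal(unname(meuwissen_luo_f(pedigree_table(df))["x"]), 0)
  gd <- gene_drop_ancestral(pedigree_table(df), rounds = 500, seed = 1,
                            target_se = 0.05)
  expect_equal(gd[gd$iid == "x", "f_ped_drop"], 0)
})
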
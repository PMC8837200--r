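test_that("trait models validate their covariance matrices", {
  expect_error(trait_model("a", G = matrix(-1, 1, 1), PE = 0.1, GROUP = 0.1,
                           R = 0.1),
               "positive semi-definite")
  tm <- trait_model(c("a", "b"), G = c(1, 2), PE = c(0.5, 0.5),
                    GROUP = c(0.1, 0.1), R = c(1, 1))
  expect_equal(diag(tm$G), c(a = 1, b = 2))
})

test_that("breeding values have pedigree-structured covariance", {
  ## zero genetic variance -> exactly zero deviations
  ped <- small_ped()
  bv0 <- sample_breeding_values(ped, matrix(0, 1, 1), seed = 1)
  expect_true(all(bv0 == 0))

  ## founders only: iid draws with the right variance
  founders <- as_pedigree(data.frame(id = paste0("f", 1:5000),
                                     sire = NA, dam = NA))
  bv <- sample_breeding_values(founders, 1, seed = 2)
  expect_equal(stats::var(as.numeric(bv)), 1, tolerance = 0.05)

  ## half-sib design: variance of sire-family means approaches Va/4
  hs <- simulate_pedigree(n_generations = 1, n_sires = 150,
                          dams_per_sire = 8, offspring_per_dam = 1, seed = 3)
  va <- 2
  bvh <- sample_breeding_values(hs, va, seed = 4)
  off <- hs[hs$generation == 1, ]
  fam_means <- tapply(bvh[off$id, 1], off$sire, mean)
  ## Var(family mean of k half sibs) = Va/4 + (3/4)Va/k
  k <- 8
  expect_equal(stats::var(as.numeric(fam_means)), va / 4 + 0.75 * va / k,
               tolerance = 0.25)

  ## stacked covariance equals A (x) G: empirical check on a tiny pedigree
  tiny <- as_pedigree(data.frame(
    id = c("s", "d", "o1", "o2", "x"),
    sire = c(NA, NA, "s", "s", "o1"),
    dam = c(NA, NA, "d", "d", NA)))
  A <- additive_relationship_matrix(tiny)
  reps <- vapply(1:4000, function(r) {
    sample_breeding_values(tiny, 1, seed = r)[, 1]
  }, numeric(5))
  emp <- stats::cov(t(reps))
  expect_lt(max(abs(emp - A)), 0.12)

  ## deterministic under a fixed seed
  expect_identical(sample_breeding_values(ped, 1.5, seed = 9),
                   sample_breeding_values(ped, 1.5, seed = 9))
})

test_that("group assignment respects sizes, sexes and family dispersion", {
  ped <- simulate_pedigree(n_generations = 1, n_sires = 2, dams_per_sire = 4,
                           offspring_per_dam = 5, seed = 7)
  g <- assign_groups(ped, study_design(group_size_range = c(16, 20)),
                     seed = 1)
  expect_equal(length(unique(g$group)), 2)
  expect_true(all(table(g$group) >= 16 & table(g$group) <= 20))

  ## 17 fish fit in a single legal group
  ped17 <- as_pedigree(data.frame(id = paste0("i", 1:17), sire = NA,
                                  dam = NA, sex = rep(c("M", "F"),
                                                      length.out = 17),
                                  generation = 0))
  g17 <- assign_groups(ped17, subset = ped17$id, seed = 2)
  expect_equal(unname(table(g17$group)), 17, ignore_attr = TRUE)

  ## sexes balanced to +-1 per group; families dispersed
  ped2 <- simulate_pedigree(n_generations = 1, n_sires = 4,
                            dams_per_sire = 4, offspring_per_dam = 10,
                            seed = 8)
  g2 <- assign_groups(ped2, study_design(group_size_range = c(16, 20)),
                      seed = 3)
  d2 <- merge(g2, as.data.frame(ped2), by = "id")
  sex_tab <- table(d2$group, d2$sex)
  expect_true(all(abs(sex_tab[, "M"] - sex_tab[, "F"]) <= 2))
  fam_tab <- table(paste(d2$sire, d2$dam), d2$group)
  fam_sizes <- rowSums(fam_tab)
  small_fams <- fam_sizes <= 10
  expect_true(all(fam_tab[small_fams, ] / fam_sizes[small_fams] <= 0.5))

  expect_error(assign_groups(ped, subset = ped$id[1]), "not enough")
})

test_that("covariates have the promised structure and determinism", {
  ped <- as_pedigree(data.frame(id = paste0("i", 1:18), sire = NA, dam = NA,
                                sex = rep(c("M", "F"), 9), generation = 0))
  g <- data.frame(id = ped$id, group = "g1")
  cov <- simulate_covariates(g, n_trials = 2, seed = 5)
  for (tr in 1:2) {
    expect_setequal(cov$order_caught[cov$rep == tr], 1:18)
  }
  expect_lt(abs(mean(cov$temperature_z)), 1e-10)
  expect_equal(stats::sd(cov$temperature_z), 1, tolerance = 1e-8)
  expect_identical(cov, simulate_covariates(g, n_trials = 2, seed = 5))
})

test_that("zero-variance models give constant phenotypes at the means", {
  ped <- small_ped()
  tm <- trait_model(c("t1", "t2"), G = c(0, 0), PE = c(0, 0),
                    GROUP = c(0, 0), R = c(0, 0),
                    means = c(t1 = 5, t2 = -3))
  st <- simulate_study(ped = ped, A = small_A(), behaviour = tm,
                       cort = cortisol_gxe_model(va1 = 0, va3 = 0, ra13 = 0,
                                                 vgroup1 = 0, vgroup3 = 0,
                                                 vr1 = 0, vr3 = 0),
                       seed = 3, include_all = TRUE)
  ph <- st$phenotypes
  expect_equal(unique(ph$value[ph$trait == "t1"]), 5)
  expect_equal(unique(ph$value[ph$trait == "t2"]), -3)
  expect_equal(unique(ph$value[ph$trait == "ln_cortisol1"]), 8.47)
  expect_equal(unique(ph$value[ph$trait == "ln_cortisol3"]), 8.02)
})

test_that("simulated phenotypes match their generating moments", {
  st <- small_study()
  ph <- st$phenotypes

  ## cortisol habituation: context-1 mean exceeds context-3 by ~0.45
  m1 <- mean(ph$value[ph$trait == "ln_cortisol1"])
  m3 <- mean(ph$value[ph$trait == "ln_cortisol3"])
  expect_lt(abs((m1 - m3) - (8.47 - 8.02)), 0.25)

  ## total phenotypic variance of sqrt(freezings) ~ sum of components
  v <- guppy_variance_components()
  tot <- sum(v[v$trait == "sqrt_freezings", c("va", "vpe", "vgroup",
                                              "vresidual")])
  obs <- stats::var(ph$value[ph$trait == "sqrt_freezings"])
  expect_equal(obs, tot, tolerance = 0.35 * tot)

  ## study generation is byte-identical under the same seed
  st2 <- simulate_study(ped = small_ped(), A = small_A(), seed = 202,
                        include_all = TRUE)
  expect_identical(st$phenotypes, st2$phenotypes)
})

test_that("realised cross-context genetic correlation tracks ra13", {
  hs <- simulate_pedigree(n_generations = 1, n_sires = 100,
                          dams_per_sire = 4, offspring_per_dam = 2, seed = 31)
  cm <- cortisol_gxe_model()
  Gc <- matrix(c(cm$va1, cm$ra13 * sqrt(cm$va1 * cm$va3),
                 cm$ra13 * sqrt(cm$va1 * cm$va3), cm$va3), 2, 2)
  bv <- sample_breeding_values(hs, Gc, seed = 32)
  expect_equal(stats::cor(bv[, 1], bv[, 2]), cm$ra13, tolerance = 0.05)
})

test_that("studies round-trip to disk", {
  st <- small_study()
  dir <- tempfile()
  write_study(st, dir)
  expect_true(file.exists(file.path(dir, "pedigree.csv")))
  ped2 <- read_pedigree(file.path(dir, "pedigree.csv"))
  expect_equal(ped2$id, st$pedigree$id)
  ph2 <- utils::read.csv(file.path(dir, "phenotypes.csv"))
  expect_equal(nrow(ph2), nrow(st$phenotypes))
  truth <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(truth$cort$ra13, 0.83)
})
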
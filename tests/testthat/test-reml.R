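# a compact univariate animal-model dataset used across several blocks
uni_data <- function() {
  fixture("uni_data", function() {
    st <- small_study()
    d <- st$phenotypes[st$phenotypes$trait == "sqrt_freezings", ]
    list(d = d, A = small_A())
  })
}

test_that("analytic gradients match finite differences", {
  ud <- uni_data()
  ## generic engine, univariate model with all four components
  fr <- qgstress:::.qg_frame(ud$d, "sqrt_freezings", fixed = ~ rep + sex,
                             A = ud$A,
                             random = list(genetic = "us", pe = "us",
                                           group = "diag"))
  sc <- qgstress:::.frame_scaffold(fr)
  info <- qgstress:::.frame_par_info(fr)
  for (p0 in list(qgstress:::.frame_start(fr),
                  qgstress:::.frame_start(fr) + c(0.3, -0.4, 0.2, -0.1))) {
    cache <- new.env(parent = emptyenv())
    g_an <- qgstress:::.gen_grad(p0, fr, sc, info, cache)
    g_fd <- vapply(seq_along(p0), function(j) {
      h <- 1e-6
      pp <- p0
      pm <- p0
      pp[j] <- pp[j] + h
      pm[j] <- pm[j] - h
      (qgstress:::.gen_eval(pp, fr, sc, info) -
         qgstress:::.gen_eval(pm, fr, sc, info)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g_an - g_fd)), 1e-4 * max(1, max(abs(g_fd))))
    ## fast univariate engine gradient at the same point
    stu <- qgstress:::.uni_setup(fr)
    gu <- qgstress:::.uni_grad(p0, fr, stu, new.env(parent = emptyenv()))
    expect_lt(max(abs(gu - g_fd)), 1e-4 * max(1, max(abs(g_fd))))
  }

  ## bivariate model with residual covariance block: checks the loading and
  ## residual-block parts of the generic gradient
  st <- small_study()
  d2 <- st$phenotypes[st$phenotypes$trait %in% c("rel_area",
                                                 "time_in_middle"), ]
  fr2 <- qgstress:::.qg_frame(d2, c("rel_area", "time_in_middle"),
                              fixed = ~rep, A = ud$A,
                              random = list(genetic = "us", pe = "diag",
                                            group = "diag"),
                              residual_blocks = list(c("rel_area",
                                                       "time_in_middle")))
  sc2 <- qgstress:::.frame_scaffold(fr2)
  info2 <- qgstress:::.frame_par_info(fr2)
  p0 <- qgstress:::.frame_start(fr2)
  p0 <- p0 + seq(-0.2, 0.2, length.out = length(p0))
  cache <- new.env(parent = emptyenv())
  g_an <- qgstress:::.gen_grad(p0, fr2, sc2, info2, cache)
  g_fd <- vapply(seq_along(p0), function(j) {
    h <- 1e-6
    pp <- p0
    pm <- p0
    pp[j] <- pp[j] + h
    pm[j] <- pm[j] - h
    (qgstress:::.gen_eval(pp, fr2, sc2, info2) -
       qgstress:::.gen_eval(pm, fr2, sc2, info2)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g_an - g_fd)), 1e-4 * max(1, max(abs(g_fd))))
})

test_that("all three engines agree on the restricted likelihood", {
  ud <- uni_data()
  fu <- reml_fit(ud$d, "sqrt_freezings", fixed = ~ rep + sex, A = ud$A,
                 engine = "uni")
  fg <- reml_fit(ud$d, "sqrt_freezings", fixed = ~ rep + sex, A = ud$A,
                 engine = "generic")
  expect_equal(fu$logLik, fg$logLik, tolerance = 1e-7)
  expect_equal(fu$components$genetic[1, 1], fg$components$genetic[1, 1],
               tolerance = 1e-4)

  st <- small_study()
  dc <- st$phenotypes[st$phenotypes$trait %in% c("ln_cortisol1",
                                                 "ln_cortisol3"), ]
  dc$occasion <- dc$id
  args <- list(data = dc, traits = c("ln_cortisol1", "ln_cortisol3"),
               fixed = ~sex, A = ud$A,
               random = list(genetic = "us", group = "diag"),
               residual_blocks = list(c("ln_cortisol1", "ln_cortisol3")))
  fp <- do.call(reml_fit, c(args, list(engine = "paired")))
  fg2 <- do.call(reml_fit, c(args, list(engine = "generic")))
  expect_equal(fp$logLik, fg2$logLik, tolerance = 1e-6)
  expect_equal(fp$components$genetic, fg2$components$genetic,
               tolerance = 1e-3)
})

test_that("REML matches lme4 on a pedigree-free and a pedigree model", {
  skip_if_not_installed("lme4")
  ud <- uni_data()
  d <- ud$d

  ## lme4 oracle with the A-structure folded into Z via its Cholesky factor
  lme4_animal <- function(d, A) {
    d$id_a <- factor(d$id)
    d$id_pe <- factor(d$id)
    d$grp <- factor(d$group)
    lf <- lme4::lFormula(value ~ rep + sex + (1 | id_a) + (1 | id_pe) +
                           (1 | grp),
                         data = d, REML = TRUE,
                         control = lme4::lmerControl(
                           check.nobs.vs.nlev = "ignore",
                           check.nobs.vs.nRE = "ignore"))
    Gp <- lf$reTrms$Gp
    b <- which(names(lf$reTrms$cnms) == "id_a")
    idx <- (Gp[b] + 1):Gp[b + 1]
    lev <- levels(lf$reTrms$flist$id_a)
    lf$reTrms$Zt[idx, ] <- methods::as(
      chol(A[lev, lev]) %*% lf$reTrms$Zt[idx, , drop = FALSE],
      "CsparseMatrix")
    devf <- do.call(lme4::mkLmerDevfun, lf)
    opt <- lme4::optimizeLmer(devf)
    m <- lme4::mkMerMod(environment(devf), opt, lf$reTrms, fr = lf$fr)
    vc <- as.data.frame(lme4::VarCorr(m))
    stats::setNames(vc$vcov, vc$grp)
  }
  vc <- lme4_animal(d, ud$A)
  fit <- reml_fit(d, "sqrt_freezings", fixed = ~ rep + sex, A = ud$A,
                  random = list(genetic = "us", pe = "us", group = "us"))
  expect_equal(fit$components$genetic[1, 1], unname(vc["id_a"]),
               tolerance = 1e-3)
  expect_equal(fit$components$pe[1, 1], unname(vc["id_pe"]),
               tolerance = 1e-3)
  expect_equal(fit$components$residual[1, 1], unname(vc["Residual"]),
               tolerance = 1e-3)
})

test_that("balanced half-sib REML equals the ANOVA sire-model estimator", {
  ## balanced paternal half-sib design: s sires, k offspring each, no other
  ## structure; the animal model Va must equal 4x the one-way ANOVA sire
  ## variance (MSB - MSW)/k exactly
  s_n <- 40
  k <- 12
  ped <- simulate_pedigree(n_generations = 1, n_sires = s_n,
                           dams_per_sire = k, offspring_per_dam = 1,
                           seed = 55)
  A <- additive_relationship_matrix(ped)
  off <- ped$id[ped$generation == 1]
  bv <- sample_breeding_values(ped, 1.2, seed = 56)
  set.seed(57)
  d <- data.frame(id = off, trait = "y",
                  value = 10 + bv[off, 1] + rnorm(length(off), 0, sqrt(2)))
  fit <- reml_fit(d, "y", fixed = ~1, A = A,
                  random = list(genetic = "us"),
                  control = qg_control(rel_tol = 1e-14))
  va <- fit$components$genetic[1, 1]

  sire <- ped$sire[match(off, ped$id)]
  aov_fit <- stats::aov(d$value ~ factor(sire))
  ms <- summary(aov_fit)[[1]]$`Mean Sq`
  va_anova <- 4 * (ms[1] - ms[2]) / k
  expect_gt(va_anova, 0)  # interior estimate, identity applies
  expect_equal(va, va_anova, tolerance = 1e-6)
})

test_that("restricted likelihood is invariant to row order and labels", {
  ud <- uni_data()
  fit <- reml_fit(ud$d, "sqrt_freezings", fixed = ~rep, A = ud$A)
  set.seed(1)
  d2 <- ud$d[sample.int(nrow(ud$d)), ]
  fit2 <- reml_fit(d2, "sqrt_freezings", fixed = ~rep, A = ud$A)
  expect_equal(fit$logLik, fit2$logLik, tolerance = 1e-7)

  ## relabel individuals consistently in data and A
  d3 <- ud$d
  map <- stats::setNames(paste0("fish_", seq_along(unique(d3$id))),
                         unique(d3$id))
  d3$id <- unname(map[d3$id])
  A3 <- ud$A
  rownames(A3) <- colnames(A3) <- unname(map[rownames(ud$A)])
  fit3 <- reml_fit(d3, "sqrt_freezings", fixed = ~rep, A = A3)
  expect_equal(fit$logLik, fit3$logLik, tolerance = 1e-7)
})

test_that("constrained genetic structures never beat the unstructured fit", {
  st <- small_study()
  dc <- st$phenotypes[st$phenotypes$trait %in% c("ln_cortisol1",
                                                 "ln_cortisol3"), ]
  dc$occasion <- dc$id
  args <- list(data = dc, traits = c("ln_cortisol1", "ln_cortisol3"),
               fixed = ~1, A = small_A(),
               residual_blocks = list(c("ln_cortisol1", "ln_cortisol3")))
  f_us <- do.call(reml_fit, c(args, list(random = list(genetic = "us",
                                                       group = "diag"))))
  f_r1 <- do.call(reml_fit, c(args, list(random = list(genetic = "rank1",
                                                       group = "diag"))))
  f_sh <- do.call(reml_fit, c(args, list(random = list(genetic = "shared",
                                                       group = "diag"))))
  expect_lte(f_r1$logLik, f_us$logLik + 1e-4)
  expect_lte(f_sh$logLik, f_r1$logLik + 1e-4)
  ## rank-1 G has correlation +-1 by construction
  G <- f_r1$components$genetic
  expect_equal(abs(G[1, 2]) / sqrt(G[1, 1] * G[2, 2]), 1, tolerance = 1e-6)
})

test_that("a zero-variance truth drives the genetic component to boundary", {
  ped <- small_ped()
  tm <- trait_model("flat", G = 0, PE = 0.3, GROUP = 0.1, R = 1)
  st <- simulate_study(ped = ped, A = small_A(), behaviour = tm, seed = 77,
                       include_all = TRUE)
  d <- st$phenotypes[st$phenotypes$trait == "flat", ]
  fit <- reml_fit(d, "flat", fixed = ~1, A = small_A())
  vp <- sum(vapply(fit$components, function(S) S[1, 1], numeric(1)))
  expect_lt(fit$components$genetic[1, 1], 1e-3 * vp)
})

test_that("BLUPs shrink correctly and flow through the pedigree", {
  ped <- small_ped()
  A <- small_A()
  bv <- sample_breeding_values(ped, 0.6, seed = 91)
  ids <- ped$id[ped$generation == 2]
  set.seed(92)
  d <- do.call(rbind, lapply(ids, function(i) {
    data.frame(id = i, trait = "y", rep = 1:3,
               value = bv[i, 1] + rnorm(3, 0, sqrt(0.6)))
  }))
  fit <- reml_fit(d, "y", fixed = ~1, A = A,
                  random = list(genetic = "us", pe = "us"))
  b <- blup(fit, "genetic", A = A)
  ## calibration: regression of true breeding values on BLUPs ~ 1
  bb <- b[match(ids, b$id), ]
  sl <- stats::coef(stats::lm(bv[ids, 1] ~ bb$blup))[2]
  expect_equal(unname(sl), 1, tolerance = 0.25)
  ## unphenotyped parents still get nonzero predictions via A
  parents <- unique(stats::na.omit(c(ped$sire[match(ids, ped$id)])))
  bp <- b$blup[match(parents, b$id)]
  expect_true(all(is.finite(bp)))
  expect_gt(stats::sd(bp), 0)
  ## parent prediction = mean of a large offspring family's signal direction
  expect_gt(stats::cor(bp, tapply(bv[ids, 1],
                                  ped$sire[match(ids, ped$id)],
                                  mean)[parents]), 0.5)

  ## shrinkage limit: near-zero Va pushes all genetic BLUPs to ~0
  tm <- trait_model("flat", G = 0, PE = 0.5, GROUP = 0, R = 1)
  st0 <- simulate_study(ped = ped, A = A, behaviour = tm, seed = 93,
                        include_all = TRUE)
  d0 <- st0$phenotypes[st0$phenotypes$trait == "flat", ]
  fit0 <- reml_fit(d0, "flat", fixed = ~1, A = A,
                   random = list(genetic = "us", pe = "us"))
  expect_lt(max(abs(blup(fit0, "genetic")$blup)), 1e-2)
})

test_that("Wald F reduces to the squared OLS t in the fixed-only case", {
  set.seed(13)
  n <- 60
  d <- data.frame(id = paste0("i", 1:n), trait = "y", x = rnorm(n))
  d$value <- 2 + 0.4 * d$x + rnorm(n)
  fit <- reml_fit(d, "y", fixed = ~x, A = NULL, random = list(),
                  se = TRUE)
  w <- wald_fixed(fit, c(0, 1))
  ols <- summary(stats::lm(value ~ x, d))$coefficients
  expect_equal(w$F, ols["x", "t value"]^2, tolerance = 1e-6)
  expect_equal(w$df2, n - 2, tolerance = 0.02 * (n - 2))
  expect_equal(w$estimate, ols["x", "Estimate"], tolerance = 1e-6)
})

test_that("simulated responses reproduce the fitted covariance structure", {
  ud <- uni_data()
  fit <- reml_fit(ud$d, "sqrt_freezings", fixed = ~rep, A = ud$A)
  s1 <- simulate_response(fit, seed = 4)
  s2 <- simulate_response(fit, seed = 4)
  expect_identical(s1$value, s2$value)
  expect_false(identical(s1$value, simulate_response(fit, seed = 5)$value))
  ## phenotypic variance of simulations ~ fitted total variance
  vtot <- sum(vapply(fit$components, function(S) S[1, 1], numeric(1)))
  vs <- mean(vapply(1:20, function(r) {
    stats::var(simulate_response(fit, seed = r)$value)
  }, numeric(1)))
  expect_equal(vs, vtot, tolerance = 0.25 * vtot)
})
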
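#' Synthetic study generation
#'
#' Generates complete synthetic quantitative-genetic studies — pedigree,
#' housing groups, assay covariates, repeated multivariate behavioural
#' phenotypes and two-context cortisol measures — with the statistical
#' structure the animal-model pipeline assumes: additive genetic effects
#' structured by the pedigree, permanent-environment and housing-group
#' effects shared across repeat trials, independent trial-level residuals,
#' and a cross-context genetic correlation for cortisol
#' (genotype-by-environment structure in stressor habituation).
#'
#' @name synthetic_data
NULL

#' Trait model: covariance structure and fixed effects of simulated traits
#'
#' Defaults are point estimates from a published quantitative-genetic study
#' of guppy stress-response behaviour (univariate variance components for
#' six behavioural traits plus ln cortisol), so that estimation code can be
#' exercised against realistic parameter values. All matrices are on the
#' analysis scale of each trait (square-root freezings, ln emergence time,
#' ln cortisol).
#'
#' @param traits trait names.
#' @param G,PE,GROUP,R trait-level covariance matrices (numeric scalars are
#'   promoted to diagonal matrices).
#' @param means per-trait intercepts.
#' @param fixed_effects named list mapping covariate name to a per-trait
#'   coefficient vector.
#' @return object of class `trait_model`.
#' @export
trait_model <- function(traits, G, PE, GROUP, R, means = NULL,
                        fixed_effects = NULL) {
  t_n <- length(traits)
  fix <- function(M) {
    if (is.null(dim(M))) M <- diag(M, t_n, t_n)
    stopifnot(nrow(M) == t_n, ncol(M) == t_n)
    M <- (M + t(M)) / 2
    if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop("covariance matrix is not positive semi-definite")
    }
    dimnames(M) <- list(traits, traits)
    M
  }
  if (is.null(means)) means <- stats::setNames(rep(0, t_n), traits)
  structure(list(traits = traits, G = fix(G), PE = fix(PE),
                 GROUP = fix(GROUP), R = fix(R),
                 means = means, fixed_effects = fixed_effects),
            class = "trait_model")
}

#' Default univariate variance components for the emulated study
#'
#' Point estimates (additive genetic, permanent environment, group and
#' residual variances) for the six behavioural traits and ln cortisol, as
#' published for the guppy stress-response study this generator emulates.
#'
#' @return data frame with one row per trait.
#' @export
guppy_variance_components <- function() {
  data.frame(
    trait = c("rel_area", "time_in_middle", "track_length", "sqrt_freezings",
              "ln_emergence", "shoaling", "ln_cortisol"),
    va = c(42.87, 554.78, 23584.54, 0.34, 0.12, 0, 0.08),
    vpe = c(56.16, 473.24, 26587.74, 0.18, 0.06, 2457.36, 0.02),
    vgroup = c(19.17, 196.94, 3173.34, 0.08, 0.05, 708.87, 0.01),
    vresidual = c(203.17, 2002.06, 76140.49, 1.13, 1.07, 9900.95, 0.15),
    stringsAsFactors = FALSE
  )
}

#' Published additive genetic covariance matrix for six stress-response traits
#'
#' The 6 x 6 additive genetic covariance matrix (traits standardised to
#' phenotypic SD units; emergence time ln-transformed and sign-flipped so
#' high values mean fast emergence) estimated by the multivariate animal
#' model of the study this package emulates. Variances on the diagonal,
#' covariances off it.
#'
#' @return symmetric labelled matrix.
#' @export
guppy_g_matrix <- function() {
  traits <- c("rel_area", "time_in_middle", "track_length", "sqrt_freezings",
              "neg_ln_emergence", "ln_cortisol")
  g <- matrix(0, 6, 6, dimnames = list(traits, traits))
  diag(g) <- c(0.115, 0.145, 0.147, 0.185, 0.076, 0.121)
  g[lower.tri(g)] <- c(0.103, -0.071, 0.020, -0.041, -0.044,
                       -0.096, 0.059, -0.016, -0.082,
                       -0.132, 0.065, 0.057,
                       -0.057, -0.083,
                       -0.002)
  g[upper.tri(g)] <- t(g)[upper.tri(g)]
  g
}

#' Cortisol character-state (GxE) model
#'
#' Two-context model for ln cortisol following the first and third exposure
#' to a handling-and-confinement stressor: context-specific means, additive
#' genetic variances with a cross-context genetic correlation, group
#' variances and residual variances. Defaults are the published point
#' estimates of the emulated study (ln ng/hr scale).
#'
#' @param mu1,mu3 context means.
#' @param va1,va3 context-specific additive genetic variances.
#' @param ra13 cross-context genetic correlation.
#' @param vgroup1,vgroup3 group variances.
#' @param vr1,vr3 residual variances.
#' @return object of class `cortisol_gxe_model`.
#' @export
cortisol_gxe_model <- function(mu1 = 8.47, mu3 = 8.02,
                               va1 = 0.081, va3 = 0.041, ra13 = 0.83,
                               vgroup1 = 0.038, vgroup3 = 0.032,
                               vr1 = 0.164, vr3 = 0.237) {
  stopifnot(va1 >= 0, va3 >= 0, abs(ra13) <= 1,
            vgroup1 >= 0, vgroup3 >= 0, vr1 >= 0, vr3 >= 0)
  structure(list(mu1 = mu1, mu3 = mu3, va1 = va1, va3 = va3, ra13 = ra13,
                 vgroup1 = vgroup1, vgroup3 = vgroup3, vr1 = vr1, vr3 = vr3),
            class = "cortisol_gxe_model")
}

#' Study design: grouping, repeat trials and assay inclusion
#'
#' @param group_size_range admissible housing-group sizes (mixed-sex groups
#'   of adults).
#' @param trials list of repeat counts per assay (`oft`, `et`, `st`,
#'   `cortisol` contexts are fixed at 2: first and third stressor exposure).
#' @param include probability that a fish enters each assay (emulating that
#'   not every fish was measured for every assay).
#' @return object of class `study_design`.
#' @export
study_design <- function(group_size_range = c(16, 20),
                         trials = list(oft = 2, et = 2, st = 2),
                         include = c(oft = 0.99, et = 0.6, st = 0.4,
                                     cortisol = 0.45)) {
  stopifnot(length(group_size_range) == 2,
            group_size_range[1] <= group_size_range[2])
  structure(list(group_size_range = group_size_range, trials = trials,
                 include = include), class = "study_design")
}

#' Sample additive-genetic deviations down a pedigree
#'
#' Founders are drawn from `MVN(0, G)`; each non-founder receives the mean
#' of its parents' values plus a Mendelian-sampling deviation with
#' covariance `(1 - (F_s + F_d)/2) / 2 * G` (an unknown parent contributes
#' a fresh founder draw, i.e. its share of the variance is not reduced).
#' The stacked values then have covariance `A (x) G` exactly.
#'
#' @param ped a [pedigree].
#' @param G trait covariance matrix (scalar allowed).
#' @param seed integer seed.
#' @param Fcoef optional named vector of inbreeding coefficients (taken from
#'   the A diagonal when omitted).
#' @return matrix (individuals x traits), rownames from the pedigree.
#' @export
sample_breeding_values <- function(ped, G, seed = 1, Fcoef = NULL) {
  if (!inherits(ped, "pedigree")) ped <- as_pedigree(ped)
  if (is.null(dim(G))) G <- matrix(G, 1, 1)
  t_n <- nrow(G)
  eg <- eigen(G, symmetric = TRUE)
  if (min(eg$values) < -1e-8) stop("G must be positive semi-definite")
  Gh <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), t_n) %*% t(eg$vectors)

  if (is.null(Fcoef)) {
    Fcoef <- diag(additive_relationship_matrix(ped)) - 1
  } else {
    Fcoef <- Fcoef[ped$id]
  }
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])

  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)
  Zm <- matrix(stats::rnorm(n * t_n), n, t_n)

  BV <- matrix(0, n, t_n, dimnames = list(ped$id, colnames(G)))
  for (i in seq_len(n)) {
    mean_i <- numeric(t_n)
    vshare <- 1
    if (!is.na(si[i])) {
      mean_i <- mean_i + 0.5 * BV[si[i], ]
      vshare <- vshare - 0.25 * (1 + Fcoef[si[i]])
    }
    if (!is.na(di[i])) {
      mean_i <- mean_i + 0.5 * BV[di[i], ]
      vshare <- vshare - 0.25 * (1 + Fcoef[di[i]])
    }
    BV[i, ] <- mean_i + sqrt(max(vshare, 0)) * (Gh %*% Zm[i, ])[, 1]
  }
  BV
}

#' Assign individuals to mixed-family housing groups
#'
#' Groups are filled to sizes inside the design's admissible range, with
#' sexes balanced to within one fish and full-sib families dispersed across
#' groups (members of a family are dealt round-robin).
#'
#' @param ped a [pedigree]; the individuals to house are selected with
#'   `subset` (default: the final generation).
#' @param design a [study_design()].
#' @param seed integer seed.
#' @param subset character vector of ids to house.
#' @return data frame with columns `id`, `group`.
#' @export
assign_groups <- function(ped, design = study_design(), seed = 1,
                          subset = NULL) {
  if (is.null(subset)) {
    subset <- ped$id[ped$generation == max(ped$generation, na.rm = TRUE)]
  }
  d <- ped[match(subset, ped$id), , drop = FALSE]
  N <- nrow(d)
  lo <- design$group_size_range[1]
  hi <- design$group_size_range[2]
  if (N < lo) {
    if (N < 2) stop("not enough individuals to form a housing group")
    warning("fewer individuals than the minimum group size; one small group")
    return(data.frame(id = d$id, group = "g1", stringsAsFactors = FALSE))
  }
  n_groups <- max(1, ceiling(N / hi))
  if (N / n_groups < lo) n_groups <- max(1, floor(N / lo))

  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)

  ## greedy assignment: place individuals (in random order) into the group
  ## that currently holds the fewest members of their full-sib family,
  ## breaking ties towards deficient sexes and then towards smaller groups,
  ## under exact capacity targets
  fam <- factor(paste(ifelse(is.na(d$sire), "NA", d$sire),
                      ifelse(is.na(d$dam), "NA", d$dam)))
  sexv <- ifelse(is.na(d$sex), "U", d$sex)
  cap <- rep(floor(N / n_groups), n_groups)
  extra <- N - sum(cap)
  if (extra > 0) cap[seq_len(extra)] <- cap[seq_len(extra)] + 1
  if (any(cap > hi) || any(cap < lo)) {
    warning("could not meet the group-size range exactly; sizes ",
            paste(range(cap), collapse = "-"))
  }
  total <- integer(n_groups)
  famcnt <- matrix(0L, n_groups, nlevels(fam))
  sexcnt <- matrix(0L, n_groups, 3,
                   dimnames = list(NULL, c("M", "F", "U")))
  assign_to <- integer(N)
  ord <- sample.int(N)
  for (i in ord) {
    open <- which(total < cap)
    score <- famcnt[open, as.integer(fam[i])] * 1e6 +
      sexcnt[open, sexv[i]] * 1e3 + total[open]
    g <- open[which.min(score)]
    assign_to[i] <- g
    total[g] <- total[g] + 1L
    famcnt[g, as.integer(fam[i])] <- famcnt[g, as.integer(fam[i])] + 1L
    sexcnt[g, sexv[i]] <- sexcnt[g, sexv[i]] + 1L
  }
  data.frame(id = d$id, group = paste0("g", assign_to),
             stringsAsFactors = FALSE)
}

#' Simulate assay covariates
#'
#' Produces per-trial covariates in the layout the fitted models expect:
#' order caught (an exact permutation within each group and assay repeat),
#' water temperature (degrees C), time of day (minutes from midnight), age
#' (days) and body mass (g), plus mean-centred/scaled versions of the
#' continuous covariates (suffix `_z`).
#'
#' @param groups data frame `id`, `group` from [assign_groups()].
#' @param n_trials trials per fish.
#' @param assay assay label.
#' @param seed integer seed.
#' @return data frame with one row per (fish, trial).
#' @export
simulate_covariates <- function(groups, n_trials = 2, assay = "oft",
                                seed = 1) {
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)
  out <- list()
  for (tr in seq_len(n_trials)) {
    for (g in unique(groups$group)) {
      ids <- groups$id[groups$group == g]
      k <- length(ids)
      out[[length(out) + 1]] <- data.frame(
        id = ids, group = g, assay = assay, rep = tr,
        order_caught = sample.int(k),
        temperature = round(stats::runif(1, 23, 24.9) +
                              stats::rnorm(k, 0, 0.05), 2),
        time_of_day = round(stats::runif(1, 540, 1020)) + seq_len(k) - 1,
        stringsAsFactors = FALSE
      )
    }
  }
  cov <- do.call(rbind, out)
  ## per-fish covariates constant across trials
  ids <- unique(groups$id)
  age0 <- stats::setNames(round(stats::rnorm(length(ids), 200, 30)), ids)
  mass <- stats::setNames(round(exp(stats::rnorm(length(ids), log(0.3), 0.25)),
                                4), ids)
  sex_tab <- NULL
  cov$age <- age0[cov$id] + (cov$rep - 1) * 2
  cov$body_mass <- mass[cov$id]
  for (v in c("order_caught", "temperature", "time_of_day", "age",
              "body_mass")) {
    z <- cov[[v]] - mean(cov[[v]])
    s <- stats::sd(cov[[v]])
    cov[[paste0(v, "_z")]] <- if (s > 0) z / s else z
  }
  cov
}

#' Simulate a complete synthetic study
#'
#' Builds the full data set the analysis pipeline consumes: a nested
#' full-sib/half-sib pedigree, housing groups for the final generation,
#' repeated multivariate behavioural trials (trait values = intercept +
#' fixed-effect contributions + genetic + permanent-environment + group +
#' trial residual, all on the analysis scale), and paired cortisol measures
#' in two stressor contexts with a cross-context genetic correlation.
#'
#' @param ped a [pedigree] (default: a three-generation design of 10 sires
#'   by 3 dams by 8 offspring, roughly 600 phenotyped fish).
#' @param behaviour a [trait_model()] for the behavioural traits; defaults to
#'   the published univariate components with independent traits.
#' @param cort a [cortisol_gxe_model()].
#' @param design a [study_design()].
#' @param seed integer seed.
#' @param include_all ignore the design's assay-inclusion probabilities and
#'   phenotype every fish for everything (useful for calibration runs).
#' @param A optional precomputed relationship matrix for `ped` (avoids
#'   rebuilding it when many studies share one pedigree).
#' @return list with elements `pedigree`, `A`, `groups`, `phenotypes`
#'   (long-format data frame: id, group, assay, occasion, rep, trait, value,
#'   covariates), and `truth` (the generating parameter objects).
#' @export
simulate_study <- function(ped = NULL, behaviour = NULL, cort =
                             cortisol_gxe_model(), design = study_design(),
                           seed = 1, include_all = FALSE, A = NULL) {
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)
  if (is.null(ped)) {
    ## ~600 phenotyped fish in the final generation: 12 paternal half-sib
    ## groups x 4 maternal full-sib families x 12 offspring
    ped <- simulate_pedigree(n_generations = 3, n_sires = 12,
                             dams_per_sire = 4, offspring_per_dam = 12,
                             unknown_paternity = 0, seed = seed + 1)
  }
  if (is.null(behaviour)) {
    vc <- guppy_variance_components()
    vc <- vc[vc$trait != "ln_cortisol", ]
    behaviour <- trait_model(
      traits = vc$trait,
      G = diag(vc$va), PE = diag(vc$vpe), GROUP = diag(vc$vgroup),
      R = diag(vc$vresidual),
      means = stats::setNames(c(30, 100, 1500, 2, 4.5, 20), vc$trait),
      fixed_effects = list(
        order_caught_z = stats::setNames(c(-1, -4, 40, 0.05, 0.05, -5),
                                         vc$trait),
        temperature_z = stats::setNames(c(0.5, 3, 30, -0.03, -0.02, 2),
                                        vc$trait),
        rep = stats::setNames(c(-0.5, -2, -20, -0.02, -0.05, -2), vc$trait)
      )
    )
  }
  t_beh <- behaviour$traits
  groups <- assign_groups(ped, design, seed = seed + 2)
  ids <- groups$id
  n_id <- length(ids)
  gmap <- stats::setNames(groups$group, groups$id)
  glev <- unique(groups$group)
  sex <- stats::setNames(ped$sex[match(ids, ped$id)], ids)

  if (is.null(A)) A <- additive_relationship_matrix(ped)
  Fcoef <- stats::setNames(diag(A) - 1, ped$id)

  ## --- behavioural traits -------------------------------------------------
  BV <- sample_breeding_values(ped, behaviour$G, seed = seed + 3,
                               Fcoef = Fcoef)
  PEv <- matrix(stats::rnorm(n_id * length(t_beh)), n_id) %*%
    .psd_sqrt(behaviour$PE)
  rownames(PEv) <- ids
  GRv <- matrix(stats::rnorm(length(glev) * length(t_beh)), length(glev)) %*%
    .psd_sqrt(behaviour$GROUP)
  rownames(GRv) <- glev

  assay_of_trait <- c(rel_area = "oft", time_in_middle = "oft",
                      track_length = "oft", sqrt_freezings = "oft",
                      ln_emergence = "et", shoaling = "st")
  assay_of_trait <- assay_of_trait[intersect(names(assay_of_trait), t_beh)]
  extra <- setdiff(t_beh, names(assay_of_trait))
  if (length(extra) > 0) {
    assay_of_trait <- c(assay_of_trait,
                        stats::setNames(rep("oft", length(extra)), extra))
  }

  sex_eff <- stats::setNames(stats::rnorm(length(t_beh), 0, 0), t_beh)
  phen <- list()
  for (as_ in unique(assay_of_trait)) {
    tr_as <- names(assay_of_trait)[assay_of_trait == as_]
    n_tr <- design$trials[[as_]]
    if (is.null(n_tr)) n_tr <- 2
    keep_ids <- ids
    if (!include_all) {
      pr <- design$include[[as_]]
      if (!is.null(pr) && !is.na(pr)) {
        keep_ids <- ids[stats::runif(n_id) < pr]
      }
    }
    if (length(keep_ids) == 0) next
    cov <- simulate_covariates(groups[groups$id %in% keep_ids, , drop = FALSE],
                               n_trials = n_tr, assay = as_,
                               seed = seed + 10 + match(as_, c("oft", "et", "st")))
    cov$occasion <- paste(as_, cov$id, cov$rep, sep = "_")
    cov$sex <- sex[cov$id]
    Rsub <- behaviour$R[tr_as, tr_as, drop = FALSE]
    Emat <- matrix(stats::rnorm(nrow(cov) * length(tr_as)), nrow(cov)) %*%
      .psd_sqrt(Rsub)
    for (j in seq_along(tr_as)) {
      trn <- tr_as[j]
      lp <- behaviour$means[[trn]]
      for (fe in names(behaviour$fixed_effects)) {
        co <- behaviour$fixed_effects[[fe]][[trn]]
        if (!is.null(co) && fe %in% names(cov)) lp <- lp + co * cov[[fe]]
      }
      val <- lp + BV[cov$id, trn] + PEv[cov$id, trn] +
        GRv[gmap[cov$id], trn] + Emat[, j]
      ph <- cov
      ph$trait <- trn
      ph$value <- val
      phen[[length(phen) + 1]] <- ph
    }
  }

  ## --- cortisol: two contexts with cross-context genetic correlation ------
  Gc <- matrix(c(cort$va1,
                 cort$ra13 * sqrt(cort$va1 * cort$va3),
                 cort$ra13 * sqrt(cort$va1 * cort$va3),
                 cort$va3), 2, 2)
  BVc <- sample_breeding_values(ped, Gc, seed = seed + 4, Fcoef = Fcoef)
  keep_ids <- ids
  if (!include_all) {
    pr <- design$include[["cortisol"]]
    if (!is.null(pr) && !is.na(pr)) keep_ids <- ids[stats::runif(n_id) < pr]
  }
  if (length(keep_ids) > 0) {
    covc <- simulate_covariates(groups[groups$id %in% keep_ids, ,
                                       drop = FALSE],
                                n_trials = 2, assay = "cortisol",
                                seed = seed + 14)
    covc$sex <- sex[covc$id]
    covc$occasion <- paste("cort", covc$id, sep = "_")
    gg1 <- stats::setNames(stats::rnorm(length(glev), 0, sqrt(cort$vgroup1)),
                           glev)
    gg3 <- stats::setNames(stats::rnorm(length(glev), 0, sqrt(cort$vgroup3)),
                           glev)
    for (ctx in c(1, 3)) {
      sel <- covc$rep == ifelse(ctx == 1, 1, 2)
      cc <- covc[sel, , drop = FALSE]
      mu <- if (ctx == 1) cort$mu1 else cort$mu3
      gv <- if (ctx == 1) gg1 else gg3
      vr <- if (ctx == 1) cort$vr1 else cort$vr3
      bv <- BVc[cc$id, ifelse(ctx == 1, 1, 2)]
      cc$trait <- paste0("ln_cortisol", ctx)
      cc$context <- ctx
      cc$value <- mu + bv + gv[gmap[cc$id]] +
        stats::rnorm(nrow(cc), 0, sqrt(vr))
      phen[[length(phen) + 1]] <- cc
    }
  }

  phenotypes <- do.call(function(...) {
    args <- list(...)
    cols <- Reduce(union, lapply(args, names))
    do.call(rbind, lapply(args, function(d) {
      for (mc in setdiff(cols, names(d))) d[[mc]] <- NA
      d[, cols]
    }))
  }, phen)
  rownames(phenotypes) <- NULL

  list(pedigree = ped, A = A,
       groups = groups, phenotypes = phenotypes,
       truth = list(behaviour = behaviour, cort = cort, design = design,
                    seed = seed))
}

#' Write a synthetic study to disk (pedigree CSV, phenotype CSV, YAML truth)
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(study$pedigree, file.path(dir, "pedigree.csv"))
  utils::write.csv(study$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  truth <- list(
    behaviour = list(traits = study$truth$behaviour$traits,
                     G = as.numeric(study$truth$behaviour$G),
                     PE = as.numeric(study$truth$behaviour$PE),
                     GROUP = as.numeric(study$truth$behaviour$GROUP),
                     R = as.numeric(study$truth$behaviour$R)),
    cort = unclass(study$truth$cort),
    seed = study$truth$seed
  )
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}

## symmetric PSD square root (exact zeros stay zero, unlike a jittered
## Cholesky)
.psd_sqrt <- function(M) {
  if (is.null(dim(M))) M <- matrix(M, 1, 1)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  out <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  dimnames(out) <- dimnames(M)
  out
}
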
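#' Heritability from fitted variance components
#'
#' Adjusted heritability: the proportion of phenotypic variance (conditional
#' on fixed effects) attributable to additive genetic variance,
#' `h2 = Va / (Va + Vpe + Vgroup + Vresidual)`, using whichever of those
#' components the model contains. The standard error is obtained by the
#' delta method from the component covariance when available.
#'
#' @param fit a `qg_fit`, or a named list/vector of variance components
#'   (`va`, and any of `vpe`, `vgroup`, `vresidual`).
#' @param trait trait name (needed for multi-trait fits).
#' @return list with `estimate` and `se` (`NA` when no covariance available).
#' @examples
#' heritability(c(va = 0.34, vpe = 0.18, vgroup = 0.08, vresidual = 1.13))
#' @export
heritability <- function(fit, trait = NULL) {
  .vc_ratio(fit, trait, numerator = "genetic")
}

#' Repeatability from fitted variance components
#'
#' `R = (Va + Vpe) / (Va + Vpe + Vgroup + Vresidual)`: the proportion of
#' phenotypic variance due to consistent differences among individuals.
#'
#' @inheritParams heritability
#' @export
repeatability <- function(fit, trait = NULL) {
  .vc_ratio(fit, trait, numerator = c("genetic", "pe"))
}

.vc_ratio <- function(fit, trait, numerator) {
  if (!inherits(fit, "qg_fit")) {
    v <- unlist(fit)
    names(v) <- sub("^v", "", names(v))
    map <- c(a = "genetic", pe = "pe", group = "group",
             residual = "residual", r = "residual", e = "residual")
    names(v) <- unname(map[names(v)])
    tot <- sum(v, na.rm = TRUE)
    num <- sum(v[names(v) %in% numerator], na.rm = TRUE)
    if (tot <= 0) stop("total phenotypic variance is zero")
    return(list(estimate = num / tot, se = NA_real_))
  }
  fr <- fit$frame
  if (is.null(trait)) {
    if (fr$t > 1) stop("specify a trait for a multi-trait fit")
    trait <- fr$traits
  }
  comp <- vapply(fit$components, function(S) S[trait, trait], numeric(1))
  if (!"genetic" %in% names(comp) && identical(numerator, "genetic")) {
    stop("fit has no genetic component")
  }
  tot <- sum(comp)
  if (tot <= 0) stop("total phenotypic variance is zero")
  num <- sum(comp[names(comp) %in% numerator])
  est <- num / tot

  se <- NA_real_
  if (!is.null(fit$component_vcov)) {
    key <- paste0(names(comp), ":", trait, ",", trait)
    present <- key %in% rownames(fit$component_vcov)
    if (all(present)) {
      Vc <- fit$component_vcov[key, key]
      g <- ifelse(names(comp) %in% numerator, (tot - num) / tot^2,
                  -num / tot^2)
      se <- sqrt(max(as.numeric(t(g) %*% Vc %*% g), 0))
    }
  }
  list(estimate = est, se = se)
}

#' Likelihood-ratio test between nested REML fits
#'
#' The statistic is twice the difference in restricted log-likelihoods
#' (clipped at zero). When the reduced model fixes a single variance
#' component at its boundary (zero), the asymptotic null distribution is an
#' equal mixture of a point mass at zero and a chi-square with one degree of
#' freedom, and the p-value is `0.5 * P(chisq_1 >= x)` (0.5 at `x = 0`).
#' Otherwise a plain chi-square with `df` equal to the parameter-count
#' difference is used.
#'
#' @param full,reduced fitted `qg_fit` objects (or numeric log-likelihoods
#'   with `df` supplied).
#' @param boundary is the tested parameter on the boundary of its space?
#' @param df degrees of freedom; computed from the fits when omitted.
#' @return list with `statistic`, `df`, `boundary`, `p_value`.
#' @examples
#' lrt_chisq(20.01 / 2, 0, df = 1, boundary = TRUE)  # p < 0.001
#' @export
lrt <- function(full, reduced, boundary = FALSE, df = NULL) {
  ll_f <- if (inherits(full, "qg_fit")) full$logLik else as.numeric(full)
  ll_r <- if (inherits(reduced, "qg_fit")) reduced$logLik else
    as.numeric(reduced)
  if (is.null(df)) {
    if (!inherits(full, "qg_fit") || !inherits(reduced, "qg_fit")) {
      stop("supply df when passing raw log-likelihoods")
    }
    df <- full$npar - reduced$npar
    if (df <= 0) stop("models do not appear to be nested (df <= 0)")
  }
  x <- 2 * (ll_f - ll_r)
  if (x < -1e-6 * max(1, abs(ll_f))) {
    warning("reduced model has higher log-likelihood than the full model; ",
            "possible convergence failure (statistic clipped at 0)")
  }
  x <- max(x, 0)
  p <- if (boundary) {
    if (df != 1) stop("the boundary mixture is implemented for df = 1")
    0.5 * stats::pchisq(x, df = 1, lower.tail = FALSE)
  } else {
    stats::pchisq(x, df = df, lower.tail = FALSE)
  }
  structure(list(statistic = x, df = df, boundary = boundary, p_value = p),
            class = "qg_lrt")
}

#' @rdname lrt
#' @param ll_full,ll_reduced restricted log-likelihoods.
#' @export
lrt_chisq <- function(ll_full, ll_reduced, df = 1, boundary = FALSE) {
  lrt(ll_full, ll_reduced, boundary = boundary, df = df)
}

#' @export
print.qg_lrt <- function(x, ...) {
  lab <- if (x$boundary) "chi2(0,1) mixture" else paste0("chi2(", x$df, ")")
  cat(sprintf("LRT: statistic = %.4g on %s, p = %.4g\n",
              x$statistic, lab, x$p_value))
  invisible(x)
}

#' Character-state (GxE) model sequence for two-context cortisol
#'
#' Fits the nested sequence of bivariate animal models used to test for
#' additive genetic variance and genotype-by-environment interaction in a
#' trait measured in two contexts (here, ln cortisol after the first and
#' third stressor exposure):
#'
#' * model 0 - no genetic effects (group and residual (co)variance only);
#' * model 1 - a single genetic effect common to both contexts
#'   (`Va1 = Va3`, cross-context correlation fixed at +1);
#' * model 2 - context-specific genetic variances, correlation still +1
#'   (one common genetic factor with free context loadings);
#' * model 3 - unstructured 2 x 2 genetic covariance (correlation free).
#'
#' Three LRTs follow the sequence: genetic variance (model 1 vs 0, boundary
#' mixture), GxE in the variances (model 2 vs 1, boundary mixture), and
#' cross-context correlation below one (model 3 vs 2, plain chi-square).
#' Individuals lacking either context are dropped (the character-state
#' likelihood requires the pair).
#'
#' @param data long-format data with one observation per individual per
#'   context; `trait` distinguishes the contexts.
#' @param A relationship matrix.
#' @param traits the two context trait names.
#' @param fixed fixed-effect formula applied per context (context-specific
#'   means are implicit in the per-trait intercepts).
#' @param se compute standard errors for the final model.
#' @param control [qg_control()].
#' @return object of class `qg_gxe`: list of `fits` (m0-m3), `tests`
#'   (`genetic`, `gxe_variance`, `correlation`), and `estimates` (context
#'   variances, cross-context genetic correlation and heritabilities from
#'   model 3).
#' @export
gxe_model_sequence <- function(data, A, traits = c("ln_cortisol1",
                                                   "ln_cortisol3"),
                               fixed = ~1, se = FALSE,
                               control = qg_control()) {
  stopifnot(length(traits) == 2)
  d <- data[data$trait %in% traits & !is.na(data$value), , drop = FALSE]
  keep <- names(which(table(unique(d[c("id", "trait")])$id) == 2))
  dropped <- setdiff(unique(d$id), keep)
  if (length(dropped) > 0) {
    message("dropping ", length(dropped),
            " individual(s) without both contexts")
    d <- d[d$id %in% keep, , drop = FALSE]
  }
  d$occasion <- d$id  # the pair of contexts shares individual-level residual

  blocks <- list(traits)
  base <- list(data = d, traits = traits, fixed = fixed, A = A,
               residual_blocks = blocks, control = control)
  fit_m <- function(gen_struct, start = NULL) {
    random <- if (is.null(gen_struct)) list(group = "diag") else
      list(genetic = gen_struct, group = "diag")
    do.call(reml_fit, c(base, list(random = random, start = start)))
  }
  ## warm-start each model from the previous (nested) one
  m0 <- fit_m(NULL)
  m1 <- fit_m("shared", start = c(0.3, m0$par))
  m2 <- fit_m("rank1", start = c(rep(m1$par[1], 2), m1$par[-1]))
  ## start the unstructured model at the rank-1 optimum, with the extra
  ## loading at its boundary (so a cross-context correlation of +1 needs no
  ## further movement, and r < 1 lifts the loading off the bound)
  lam <- m2$par[1:2]
  if (lam[1] < 0) lam <- -lam
  m3 <- fit_m("us", start = c(log(max(abs(lam[1]), 1e-3)), lam[2], -7.5,
                              m2$par[-(1:2)]))
  if (se) m3 <- add_component_se(m3)

  tests <- list(
    genetic = lrt(m1, m0, boundary = TRUE),
    gxe_variance = lrt(m2, m1, boundary = TRUE),
    correlation = lrt(m3, m2)
  )

  G <- m3$components$genetic
  Q <- m3$components$group
  R <- m3$components$residual
  va <- diag(G)
  ra <- if (all(va > 0)) G[1, 2] / sqrt(prod(va)) else NA_real_
  h2 <- va / (va + diag(Q) + diag(R))
  structure(list(fits = list(m0 = m0, m1 = m1, m2 = m2, m3 = m3),
                 tests = tests,
                 estimates = list(va = va, vgroup = diag(Q),
                                  vresidual = diag(R), ra13 = ra, h2 = h2)),
            class = "qg_gxe")
}

#' @export
print.qg_gxe <- function(x, ...) {
  cat("character-state GxE model sequence\n")
  cat(sprintf("  Va: %.4g / %.4g   r_a = %.3f\n",
              x$estimates$va[1], x$estimates$va[2], x$estimates$ra13))
  cat(sprintf("  h2: %.3f / %.3f\n", x$estimates$h2[1], x$estimates$h2[2]))
  cat("  genetic variance:      ")
  print(x$tests$genetic)
  cat("  GxE (variances):       ")
  print(x$tests$gxe_variance)
  cat("  correlation < 1:       ")
  print(x$tests$correlation)
  invisible(x)
}

#' Wald F test of a fixed-effect contrast
#'
#' Tests `L beta = 0` with an F statistic whose numerator degrees of freedom
#' equal the contrast rank. For single contrasts the denominator degrees of
#' freedom use a Satterthwaite-type approximation,
#' `df = 2 v^2 / Var(v)`, where `v = L cov(beta) L'` and its variance is
#' propagated from the variance-parameter covariance.
#'
#' @param fit a `qg_fit`.
#' @param contrast numeric vector (one contrast) or matrix (rows =
#'   contrasts) over the fixed-effect coefficients, in the order of
#'   `fit$beta`.
#' @return list with `F`, `df1`, `df2`, `p_value`, `estimate`.
#' @export
wald_fixed <- function(fit, contrast) {
  fr <- fit$frame
  L <- if (is.null(dim(contrast))) matrix(contrast, nrow = 1) else contrast
  if (ncol(L) != fr$p) stop("contrast length must equal ", fr$p)
  env <- fit$solution_env
  p <- fr$p
  scale_back <- fr$sds[fr$x_trait]
  beta <- env$s[seq_len(p)] * scale_back
  Cb <- chol2inv(env$chC)[seq_len(p), seq_len(p), drop = FALSE] *
    tcrossprod(scale_back)
  Lb <- as.numeric(L %*% beta)
  LVL <- L %*% Cb %*% t(L)
  r <- qr(L)$rank
  if (min(eigen(LVL, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("contrast is not estimable")
  }
  Fstat <- as.numeric(t(Lb) %*% solve(LVL, Lb)) / r

  df2 <- fr$n - p
  if (r == 1) {
    if (is.null(fit$vcov_theta)) fit <- add_component_se(fit)
    v_of <- function(par) {
      cache <- new.env(parent = emptyenv())
      .gen_eval(par, fr, fit$scaffold, fit$par_info, cache)
      Cb_ <- chol2inv(cache$chC)[seq_len(p), seq_len(p), drop = FALSE] *
        tcrossprod(scale_back)
      as.numeric(L %*% Cb_ %*% t(L))
    }
    h <- 1e-4 * pmax(abs(fit$par), 1)
    gvec <- vapply(seq_along(fit$par), function(j) {
      pp <- fit$par
      pm <- fit$par
      pp[j] <- pp[j] + h[j]
      pm[j] <- pm[j] - h[j]
      (v_of(pp) - v_of(pm)) / (2 * h[j])
    }, numeric(1))
    v <- as.numeric(LVL)
    var_v <- as.numeric(t(gvec) %*% fit$vcov_theta %*% gvec)
    if (is.finite(var_v) && var_v > 0) {
      df2 <- max(2 * v^2 / var_v, 1)
    }
  }
  list(F = Fstat, df1 = r, df2 = df2,
       p_value = stats::pf(Fstat, r, df2, lower.tail = FALSE),
       estimate = Lb)
}
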
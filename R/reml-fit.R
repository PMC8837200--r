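## Fitting driver for pedigree-based animal models. Three evaluation engines
## share one parameter space (per-term loading parameters, then residual
## block parameters):
##
##   generic : mixed-model equations with analytic gradients; any model
##   uni     : single trait; genetic and permanent-environment effects are
##             collapsed into one per-individual effect whose prior is
##             diagonalised by the eigendecomposition of A, making each
##             evaluation O((p + n_id + n_group)^3) with a small constant
##   paired  : one observation per trait per individual (character-state
##             models); individual-level covariance is block-diagonalised by
##             the eigendecomposition of A and the group term handled by
##             Woodbury identities
##
## All engines return the exact same -2 restricted log-likelihood, which is
## asserted in the test suite.

#' Control settings for REML fitting
#'
#' @param rel_tol relative convergence tolerance on the objective.
#' @param grad_tol gradient-norm threshold used in convergence diagnostics.
#' @param max_iter iteration cap for the optimiser.
#' @param restarts number of jittered restarts (1 = single fit from the
#'   moment-based start).
#' @param jitter standard deviation of the restart jitter on the
#'   unconstrained parameters.
#' @export
qg_control <- function(rel_tol = 1e-10, grad_tol = 1e-4, max_iter = 500,
                       restarts = 1, jitter = 0.3) {
  list(rel_tol = rel_tol, grad_tol = grad_tol, max_iter = max_iter,
       restarts = restarts, jitter = jitter)
}

## ---- engine: univariate fast path -----------------------------------------

.uni_setup <- function(fr) {
  stopifnot(fr$t == 1L)
  has_gen <- "genetic" %in% names(fr$terms)
  has_pe <- "pe" %in% names(fr$terms)
  has_grp <- "group" %in% names(fr$terms)
  n <- fr$n
  q <- if (has_gen || has_pe) length(fr$ids) else 0L
  U <- NULL
  sev <- NULL
  Zc <- NULL
  if (has_gen) {
    tm <- fr$terms$genetic
    A_obs <- if (is.null(tm$cholK)) diag(tm$q) else crossprod(tm$cholK)
    eg <- eigen(A_obs, symmetric = TRUE)
    U <- eg$vectors
    sev <- pmax(eg$values, 1e-12)
    Zc <- U[fr$id_idx, , drop = FALSE]
  } else if (has_pe) {
    sev <- rep(0, q)
    Zc <- matrix(0, n, q)
    Zc[cbind(seq_len(n), fr$id_idx)] <- 1
  }
  Zg <- NULL
  ng <- 0L
  if (has_grp) {
    ng <- fr$terms$group$q
    Zg <- matrix(0, n, ng)
    Zg[cbind(seq_len(n), fr$terms$group$lev)] <- 1
  }
  Md <- cbind(fr$X, Zc, Zg)
  list(has_gen = has_gen, has_pe = has_pe, has_grp = has_grp,
       q = q, ng = ng, sev = sev, U = U,
       MtM = crossprod(Md), Mty = crossprod(Md, fr$y)[, 1],
       yty = sum(fr$y^2), Md = Md,
       c_cols = if (q > 0) fr$p + seq_len(q) else integer(0),
       g_cols = if (ng > 0) fr$p + q + seq_len(ng) else integer(0))
}

## parameter layout matches the generic frame: [gen] [pe] [group] [resid],
## each a single log-sd
.uni_unpack <- function(st, par) {
  i <- 1L
  va <- vpe <- vg <- NA_real_
  if (st$has_gen) { va <- exp(2 * par[i]); i <- i + 1L }
  if (st$has_pe) { vpe <- exp(2 * par[i]); i <- i + 1L }
  if (st$has_grp) { vg <- exp(2 * par[i]); i <- i + 1L }
  ve <- exp(2 * par[i])
  list(va = va, vpe = vpe, vg = vg, ve = ve)
}

.uni_eval <- function(par, fr, st, env = NULL) {
  v <- .uni_unpack(st, par)
  n <- fr$n
  dc <- NULL
  if (st$q > 0) {
    dc <- rep(if (st$has_pe) v$vpe else 0, st$q) +
      (if (st$has_gen) v$va * st$sev else 0)
    if (any(dc <= 0)) return(1e10)
  }
  D <- ncol(st$MtM)
  C <- st$MtM / v$ve
  ldprior <- 0
  if (st$q > 0) {
    dg <- cbind(st$c_cols, st$c_cols)
    C[dg] <- C[dg] + 1 / dc
    ldprior <- ldprior + sum(log(dc))
  }
  if (st$ng > 0) {
    dg <- cbind(st$g_cols, st$g_cols)
    C[dg] <- C[dg] + 1 / v$vg
    ldprior <- ldprior + st$ng * log(v$vg)
  }
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  r <- st$Mty / v$ve
  s <- backsolve(ch, backsolve(ch, r, transpose = TRUE))
  quad <- st$yty / v$ve - sum(r * s)
  m2l <- (n - fr$p) * log(2 * pi) + n * log(v$ve) + ldprior +
    2 * sum(log(diag(ch))) + quad
  if (!is.finite(m2l)) return(1e10)
  if (!is.null(env)) {
    env$par <- par
    env$chC <- ch
    env$s <- s
    env$v <- v
    env$dc <- dc
    env$m2l <- m2l
  }
  m2l
}

.uni_grad <- function(par, fr, st, env) {
  if (is.null(env$par) || !identical(env$par, par)) {
    if (.uni_eval(par, fr, st, env) >= 1e10) return(rep(0, length(par)))
  }
  v <- env$v
  s <- env$s
  Cinv <- chol2inv(env$chC)
  ehat <- fr$y - as.numeric(st$Md %*% s)
  g <- numeric(length(par))
  i <- 1L
  if (st$q > 0) {
    cd <- diag(Cinv)[st$c_cols]
    sc <- s[st$c_cols]
    dpiece <- function(dd) {
      ## d(-2l) for prior diag perturbation dd (vector over c-block)
      sum(dd / env$dc) - sum(cd * dd / env$dc^2) - sum(sc^2 * dd / env$dc^2)
    }
    if (st$has_gen) {
      g[i] <- dpiece(2 * v$va * st$sev)
      i <- i + 1L
    }
    if (st$has_pe) {
      g[i] <- dpiece(rep(2 * v$vpe, st$q))
      i <- i + 1L
    }
  }
  if (st$has_grp) {
    cg <- diag(Cinv)[st$g_cols]
    sg <- s[st$g_cols]
    dd <- 2 * v$vg
    g[i] <- st$ng * dd / v$vg - sum(cg) * dd / v$vg^2 - sum(sg^2) * dd / v$vg^2
    i <- i + 1L
  }
  ## residual: d/dlog sd_e with R = ve I
  trCMM <- sum(Cinv * st$MtM)
  g[i] <- 2 * fr$n - (2 / v$ve) * trCMM - (2 / v$ve) * sum(ehat^2)
  g
}

## ---- engine: paired character-state path ----------------------------------

.paired_setup <- function(fr) {
  stopifnot(!"pe" %in% names(fr$terms), "genetic" %in% names(fr$terms))
  q <- length(fr$ids)
  t_n <- fr$t
  ## require exactly one observation per (id, trait)
  tab <- table(factor(fr$id_idx, levels = seq_len(q)),
               factor(fr$ti, levels = seq_len(t_n)))
  if (!all(tab == 1)) {
    stop("paired engine needs exactly one observation per trait per individual")
  }
  tm <- fr$terms$genetic
  A_obs <- if (is.null(tm$cholK)) diag(q) else crossprod(tm$cholK)
  eg <- eigen(A_obs, symmetric = TRUE)
  U <- eg$vectors
  sev <- pmax(eg$values, 1e-12)

  Ymat <- matrix(0, t_n, q)
  Ymat[cbind(fr$ti, fr$id_idx)] <- fr$y
  Yrot <- Ymat %*% U

  Xrot <- array(0, dim = c(t_n, q, fr$p))
  for (j in seq_len(fr$p)) {
    Xm <- matrix(0, t_n, q)
    Xm[cbind(fr$ti, fr$id_idx)] <- fr$X[, j]
    Xrot[, , j] <- Xm %*% U
  }

  has_grp <- "group" %in% names(fr$terms)
  Ug <- NULL
  ng <- 0L
  if (has_grp) {
    ## group of each individual (groups are constant within individual here)
    gi <- integer(q)
    gi[fr$id_idx] <- fr$terms$group$lev
    ng <- fr$terms$group$q
    Gm <- matrix(0, q, ng)
    Gm[cbind(seq_len(q), gi)] <- 1
    Ug <- crossprod(U, Gm)  # q x ng
  }
  list(q = q, t = t_n, U = U, sev = sev, Yrot = Yrot, Xrot = Xrot,
       has_grp = has_grp, ng = ng, Ug = Ug,
       group_struct = if (has_grp) fr$terms$group$struct else NULL,
       gen_struct = tm$struct)
}

.paired_unpack <- function(fr, st, par) {
  info <- .frame_par_info(fr)
  Lg <- .struct_load(st$gen_struct, st$t, par[info$term.genetic$idx])
  G <- tcrossprod(Lg)
  Q <- NULL
  if (st$has_grp) {
    Lq <- .struct_load(st$group_struct, st$t, par[info$term.group$idx])
    Q <- tcrossprod(Lq)
  }
  Le <- .struct_load("us", st$t, par[info$res.1$idx])
  E <- tcrossprod(Le)
  list(G = G, Q = Q, E = E)
}

.paired_eval <- function(par, fr, st, env = NULL) {
  vp <- .paired_unpack(fr, st, par)
  t_n <- st$t
  q <- st$q
  n <- q * t_n

  ## per rotated individual: B_i = s_i G + E
  Binv <- array(0, dim = c(t_n, t_n, q))
  if (t_n == 2L) {
    b11 <- st$sev * vp$G[1, 1] + vp$E[1, 1]
    b12 <- st$sev * vp$G[1, 2] + vp$E[1, 2]
    b22 <- st$sev * vp$G[2, 2] + vp$E[2, 2]
    det <- b11 * b22 - b12^2
    if (any(det <= 0) || any(b11 <= 0)) return(1e10)
    ldB <- sum(log(det))
    Binv[1, 1, ] <- b22 / det
    Binv[2, 2, ] <- b11 / det
    Binv[1, 2, ] <- Binv[2, 1, ] <- -b12 / det
  } else {
    ldB <- 0
    for (i in seq_len(q)) {
      Bi <- st$sev[i] * vp$G + vp$E
      ch <- tryCatch(chol(Bi), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      ldB <- ldB + 2 * sum(log(diag(ch)))
      Binv[, , i] <- chol2inv(ch)
    }
  }
  binv_apply <- function(Vt) {  # Vt: t x q matrix
    out <- matrix(0, t_n, q)
    for (cc in seq_len(t_n)) {
      out[cc, ] <- colSums(Binv[cc, , , drop = FALSE][1, , ] * Vt)
    }
    out
  }

  ## collect [y | X] as t x q slabs
  nrhs <- 1L + fr$p
  RHS <- array(0, dim = c(t_n, q, nrhs))
  RHS[, , 1] <- st$Yrot
  RHS[, , -1] <- st$Xrot
  BiR <- array(0, dim = c(t_n, q, nrhs))
  for (j in seq_len(nrhs)) BiR[, , j] <- binv_apply(RHS[, , j])

  if (st$has_grp) {
    Qinv <- tryCatch(solve(vp$Q), error = function(e) NULL)
    if (is.null(Qinv)) return(1e10)
    dgq <- st$ng * t_n
    ## S = Qbig^-1 + Zg' B^-1 Zg, indexed (group, context)
    S <- matrix(0, dgq, dgq)
    for (c1 in seq_len(t_n)) for (c2 in seq_len(t_n)) {
      blk <- crossprod(st$Ug, st$Ug * Binv[c1, c2, ])
      rows <- (c1 - 1L) * st$ng + seq_len(st$ng)
      cols <- (c2 - 1L) * st$ng + seq_len(st$ng)
      S[rows, cols] <- blk
    }
    for (c1 in seq_len(t_n)) for (c2 in seq_len(t_n)) {
      rows <- (c1 - 1L) * st$ng + seq_len(st$ng)
      cols <- (c2 - 1L) * st$ng + seq_len(st$ng)
      dg <- cbind(rows, cols)
      S[dg] <- S[dg] + Qinv[c1, c2]
    }
    chS <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(chS)) return(1e10)
    ## Zg' B^-1 RHS: for context c, group g: sum_i Ug[i,g] BiR[c,i,j]
    ZtBR <- array(0, dim = c(dgq, nrhs))
    for (cc in seq_len(t_n)) {
      rows <- (cc - 1L) * st$ng + seq_len(st$ng)
      ZtBR[rows, ] <- crossprod(st$Ug, matrix(BiR[cc, , ], q, nrhs))
    }
    W <- backsolve(chS, backsolve(chS, ZtBR, transpose = TRUE))
    ## V^-1 RHS = B^-1 RHS - B^-1 Zg S^-1 Zg' B^-1 RHS
    VinvR <- BiR
    for (j in seq_len(nrhs)) {
      corr <- matrix(0, t_n, q)
      for (cc in seq_len(t_n)) {
        rows <- (cc - 1L) * st$ng + seq_len(st$ng)
        corr[cc, ] <- st$Ug %*% W[rows, j]
      }
      VinvR[, , j] <- VinvR[, , j] - binv_apply(corr)
    }
    ldV <- ldB + 2 * sum(log(diag(chS))) + st$ng * determinant(vp$Q)$modulus
  } else {
    VinvR <- BiR
    ldV <- ldB
  }

  yv <- as.numeric(st$Yrot)
  XtVy <- vapply(seq_len(fr$p), function(j) {
    sum(st$Xrot[, , j] * VinvR[, , 1])
  }, numeric(1))
  XtVX <- matrix(0, fr$p, fr$p)
  for (j in seq_len(fr$p)) {
    for (k in j:fr$p) {
      XtVX[j, k] <- XtVX[k, j] <- sum(st$Xrot[, , j] * VinvR[, , 1L + k])
    }
  }
  chX <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(chX)) return(1e10)
  beta <- backsolve(chX, backsolve(chX, XtVy, transpose = TRUE))
  yVy <- sum(st$Yrot * VinvR[, , 1])
  quad <- yVy - sum(XtVy * beta)

  m2l <- (n - fr$p) * log(2 * pi) + as.numeric(ldV) +
    2 * sum(log(diag(chX))) + quad
  if (!is.finite(m2l)) return(1e10)
  if (!is.null(env)) {
    env$par <- par
    env$beta <- beta
    env$chX <- chX
    env$VinvR <- VinvR
    env$Binv <- Binv
    env$vp <- vp
    env$m2l <- m2l
  }
  m2l
}

## ---- driver ---------------------------------------------------------------

.reml_optimize <- function(obj, grad, start, lower, control) {
  best <- NULL
  for (r in seq_len(control$restarts)) {
    par0 <- start
    if (r > 1) {
      ## deterministic jitter, independent of the user RNG stream
      old <- .save_seed()
      set.seed(1000 + r)
      par0 <- start + stats::rnorm(length(start), 0, control$jitter)
      .restore_seed(old)
      par0 <- pmax(par0, lower + 0.01)
    }
    opt <- stats::nlminb(par0, obj, gradient = grad, lower = lower,
                         control = list(rel.tol = control$rel_tol,
                                        iter.max = control$max_iter,
                                        eval.max = 4 * control$max_iter))
    ## polishing pass: restarting the quasi-Newton iteration at the solution
    ## resets its curvature model and typically gains a few digits
    opt2 <- stats::nlminb(opt$par, obj, gradient = grad, lower = lower,
                          control = list(rel.tol = control$rel_tol,
                                         iter.max = control$max_iter))
    if (opt2$objective <= opt$objective) {
      opt2$iterations <- opt$iterations + opt2$iterations
      opt <- opt2
    }
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  ## Newton polish on the analytic gradient when high precision is requested
  ## (quasi-Newton line searches stop on objective flatness, which can leave
  ## variance components a few parts in 1e6 from the stationary point)
  if (!is.null(grad) && control$rel_tol < 1e-12) {
    par <- best$par
    for (it in 1:10) {
      g <- grad(par)
      free <- par > lower + 1e-6
      if (max(abs(g[free])) < 1e-9) break
      H <- matrix(0, length(par), length(par))
      h <- 1e-5 * pmax(abs(par), 1)
      for (j in which(free)) {
        pp <- par
        pm <- par
        pp[j] <- pp[j] + h[j]
        pm[j] <- pm[j] - h[j]
        H[, j] <- (grad(pp) - grad(pm)) / (2 * h[j])
      }
      Hf <- (H[free, free, drop = FALSE] + t(H[free, free, drop = FALSE])) / 2
      step <- tryCatch(-solve(Hf, g[free]), error = function(e) NULL)
      if (is.null(step)) break
      cand <- par
      cand[free] <- pmax(par[free] + step, lower[free] + 1e-8)
      if (obj(cand) <= best$objective + 1e-10) {
        par <- cand
        best$par <- par
        best$objective <- obj(par)
      } else break
    }
  }
  best
}

#' Fit a pedigree-based animal model by REML
#'
#' Fits linear mixed models with additive-genetic (pedigree-structured),
#' permanent-environment, housing-group and residual (co)variance components
#' to one or more response traits, by restricted maximum likelihood.
#' Covariance matrices are parameterised through Cholesky-type loading
#' matrices, which keeps them positive semi-definite and lets constrained
#' genetic structures (a single common factor for a cross-context genetic
#' correlation fixed at +1, say) be expressed without boundary optimisation.
#'
#' @param data long-format data frame with columns `id`, `trait`, `value`,
#'   optionally `group`, `occasion` (observations sharing an occasion may
#'   have correlated residuals) and any fixed-effect covariates.
#' @param traits character vector of trait names (order fixes trait indices).
#' @param fixed fixed-effects formula, or a named list of per-trait formulas.
#' @param A additive relationship matrix with individual labels in dimnames
#'   ([additive_relationship_matrix()]); `NULL` treats individuals as
#'   unrelated.
#' @param random named list switching on random terms and giving their
#'   covariance structure across traits: entries `genetic`, `pe`, `group`
#'   with values `"us"` (unstructured), `"diag"`, `"rank1"` (one common
#'   factor, free loadings) or `"shared"` (one common factor, one loading).
#'   Omit or set `NULL` to drop a term.
#' @param residual_blocks list of character vectors naming traits allowed to
#'   have residual covariance (they must be co-observed within occasions);
#'   all other traits get independent residuals.
#' @param scale standardise each trait internally by its raw SD before
#'   fitting (estimates are reported back on the input scale).
#' @param engine `"auto"` picks a fast specialised likelihood evaluation
#'   when the model allows it; `"generic"`, `"uni"`, `"paired"` force a path.
#' @param se compute standard errors of variance components (inverse observed
#'   information, with a delta-method transformation to the component scale).
#' @param start optional vector of starting values on the unconstrained
#'   parameter scale (e.g. to warm-start from a nested fit).
#' @param control a [qg_control()] list.
#' @return object of class `qg_fit`.
#' @export
reml_fit <- function(data, traits, fixed = ~1, A = NULL,
                     random = list(genetic = "us", pe = "us", group = "diag"),
                     residual_blocks = NULL, scale = TRUE,
                     engine = c("auto", "generic", "uni", "paired"),
                     se = FALSE, start = NULL, control = qg_control()) {
  engine <- match.arg(engine)
  fr <- .qg_frame(data, traits, fixed = fixed, A = A, random = random,
                  residual_blocks = residual_blocks, scale = scale)
  sc <- .frame_scaffold(fr)
  info <- .frame_par_info(fr)
  if (is.null(start)) start <- .frame_start(fr)
  if (length(start) != attr(info, "npar")) {
    stop("start has length ", length(start), "; expected ",
         attr(info, "npar"))
  }
  lower <- .frame_lower(fr)
  start <- pmax(start, lower + 1e-3)

  if (engine == "auto") {
    engine <- "generic"
    if (fr$t == 1L && all(vapply(fr$patterns, function(p) p$size,
                                 integer(1)) == 1L)) {
      engine <- "uni"
    } else if (!"pe" %in% names(fr$terms) && "genetic" %in% names(fr$terms) &&
                 length(fr$patterns) == 1L &&
                 fr$patterns[[1]]$size == fr$t &&
                 fr$patterns[[1]]$count == length(fr$ids)) {
      engine <- "paired"
    }
  }

  cache <- new.env(parent = emptyenv())
  if (engine == "uni") {
    st <- .uni_setup(fr)
    obj <- function(p) .uni_eval(p, fr, st, cache)
    grd <- function(p) .uni_grad(p, fr, st, cache)
  } else if (engine == "paired") {
    st <- .paired_setup(fr)
    obj <- function(p) .paired_eval(p, fr, st, cache)
    ## central differences with a step large enough to beat round-off in the
    ## flat (boundary) directions of log-scale parameters
    grd <- function(p) {
      h <- 1e-4 * pmax(abs(p), 1)
      vapply(seq_along(p), function(j) {
        pp <- p
        pm <- p
        pp[j] <- pp[j] + h[j]
        pm[j] <- pm[j] - h[j]
        (.paired_eval(pp, fr, st) - .paired_eval(pm, fr, st)) / (2 * h[j])
      }, numeric(1))
    }
  } else {
    st <- NULL
    obj <- function(p) .gen_eval(p, fr, sc, info, cache)
    grd <- function(p) .gen_grad(p, fr, sc, info, cache)
  }

  opt <- .reml_optimize(obj, grd, start, lower, control)
  par <- opt$par

  ## one generic evaluation at the optimum for solutions, beta, BLUPs
  genv <- new.env(parent = emptyenv())
  m2l <- .gen_eval(par, fr, sc, info, genv)
  if (abs(m2l - opt$objective) > 1e-4 * (1 + abs(m2l))) {
    warning("engine '", engine, "' and generic likelihood disagree (",
            format(m2l), " vs ", format(opt$objective), ")")
  }

  fit <- structure(list(
    logLik = -0.5 * m2l, npar = length(par), par = par,
    engine = engine, convergence = opt$convergence,
    message = opt$message, iterations = opt$iterations,
    frame = fr, scaffold = sc, par_info = info, solution_env = genv,
    control = control
  ), class = "qg_fit")
  fit$components <- .fit_components(fit)
  fit$beta <- .fit_beta(fit)
  if (se) fit <- add_component_se(fit)
  fit
}

## back-scaled covariance components
.fit_components <- function(fit) {
  fr <- fit$frame
  info <- fit$par_info
  Dsd <- diag(fr$sds, fr$t, fr$t)
  out <- list()
  for (nm in names(fr$terms)) {
    pi_ <- info[[paste0("term.", nm)]]
    L <- .struct_load(pi_$struct, fr$t, fit$par[pi_$idx])
    S <- Dsd %*% tcrossprod(L) %*% Dsd
    dimnames(S) <- list(fr$traits, fr$traits)
    out[[nm]] <- S
  }
  R <- matrix(0, fr$t, fr$t, dimnames = list(fr$traits, fr$traits))
  for (b in seq_along(fr$blocks)) {
    pi_ <- info[[paste0("res.", b)]]
    L <- .struct_load("us", pi_$t, fit$par[pi_$idx])
    idx <- fr$blocks[[b]]
    R[idx, idx] <- diag(fr$sds[idx], pi_$t, pi_$t) %*% tcrossprod(L) %*%
      diag(fr$sds[idx], pi_$t, pi_$t)
  }
  out$residual <- R
  out
}

.fit_beta <- function(fit) {
  fr <- fit$frame
  env <- fit$solution_env
  p <- fr$p
  beta_sc <- env$s[seq_len(p)]
  Cinv_x <- chol2inv(env$chC)[seq_len(p), seq_len(p), drop = FALSE]
  scale_back <- fr$sds[fr$x_trait]
  data.frame(term = colnames(fr$X),
             estimate = beta_sc * scale_back,
             se = sqrt(pmax(diag(Cinv_x), 0)) * scale_back,
             row.names = NULL)
}

#' @export
logLik.qg_fit <- function(object, ...) {
  structure(object$logLik, df = object$npar, nobs = object$frame$n,
            class = "logLik")
}

#' @export
print.qg_fit <- function(x, ...) {
  fr <- x$frame
  cat("REML animal model fit (", x$engine, " engine)\n", sep = "")
  cat("  traits:", paste(fr$traits, collapse = ", "), "\n")
  cat("  observations:", fr$n, " individuals:", length(fr$ids), "\n")
  cat("  logLik:", format(x$logLik, digits = 8),
      " parameters:", x$npar, "\n")
  cat("  convergence code:", x$convergence, "\n")
  invisible(x)
}

## vector of all component entries (stacked lower triangles), for delta SEs
.par_to_components <- function(par, fit) {
  fr <- fit$frame
  info <- fit$par_info
  Dsd <- fr$sds
  out <- numeric(0)
  nm_out <- character(0)
  for (nm in names(fr$terms)) {
    pi_ <- info[[paste0("term.", nm)]]
    L <- .struct_load(pi_$struct, fr$t, par[pi_$idx])
    S <- diag(Dsd, fr$t, fr$t) %*% tcrossprod(L) %*% diag(Dsd, fr$t, fr$t)
    lt <- which(lower.tri(S, diag = TRUE), arr.ind = TRUE)
    out <- c(out, S[lt])
    nm_out <- c(nm_out, paste0(nm, ":", fr$traits[lt[, 1]], ",",
                               fr$traits[lt[, 2]]))
  }
  for (b in seq_along(fr$blocks)) {
    pi_ <- info[[paste0("res.", b)]]
    L <- .struct_load("us", pi_$t, par[pi_$idx])
    idx <- fr$blocks[[b]]
    S <- diag(Dsd[idx], pi_$t, pi_$t) %*% tcrossprod(L) %*%
      diag(Dsd[idx], pi_$t, pi_$t)
    lt <- which(lower.tri(S, diag = TRUE), arr.ind = TRUE)
    out <- c(out, S[lt])
    nm_out <- c(nm_out, paste0("residual:", fr$traits[idx][lt[, 1]], ",",
                               fr$traits[idx][lt[, 2]]))
  }
  stats::setNames(out, nm_out)
}

#' Attach observed-information standard errors to a fit
#'
#' Computes the observed information of the unconstrained parameters by
#' finite differences of the analytic gradient (or of the objective for the
#' paired engine), inverts it, and propagates to the covariance-component
#' scale by a numerically differentiated delta method.
#'
#' @param fit a `qg_fit`.
#' @return the fit with elements `vcov_theta`, `component_se` and
#'   `component_vcov` added.
#' @export
add_component_se <- function(fit) {
  fr <- fit$frame
  sc <- fit$scaffold
  info <- fit$par_info
  cache <- new.env(parent = emptyenv())
  np <- fit$npar
  par <- fit$par

  if (fit$engine == "uni") {
    st <- .uni_setup(fr)
    gfun <- function(p) .uni_grad(p, fr, st, cache)
  } else if (fit$engine == "paired") {
    st <- .paired_setup(fr)
    ofun <- function(p) .paired_eval(p, fr, st, cache)
    H <- stats::optimHess(par, ofun)
    gfun <- NULL
  } else {
    gfun <- function(p) .gen_grad(p, fr, sc, info, cache)
  }
  if (!is.null(gfun)) {
    H <- matrix(0, np, np)
    hstep <- 1e-5 * pmax(abs(par), 1)
    for (j in seq_len(np)) {
      pp <- par
      pm <- par
      pp[j] <- pp[j] + hstep[j]
      pm[j] <- pm[j] - hstep[j]
      H[, j] <- (gfun(pp) - gfun(pm)) / (2 * hstep[j])
    }
    H <- (H + t(H)) / 2
  }
  ## observed information of logL is H/2 (H is hessian of -2 logL)
  Vtheta <- tryCatch(2 * solve(H), error = function(e) {
    2 * MASS::ginv(H)
  })
  ## delta method to the component scale
  comp0 <- .par_to_components(par, fit)
  J <- matrix(0, length(comp0), np)
  hstep <- 1e-6 * pmax(abs(par), 1)
  for (j in seq_len(np)) {
    pp <- par
    pm <- par
    pp[j] <- pp[j] + hstep[j]
    pm[j] <- pm[j] - hstep[j]
    J[, j] <- (.par_to_components(pp, fit) - .par_to_components(pm, fit)) /
      (2 * hstep[j])
  }
  Vc <- J %*% Vtheta %*% t(J)
  dimnames(Vc) <- list(names(comp0), names(comp0))
  fit$vcov_theta <- Vtheta
  fit$component_vcov <- Vc
  fit$component_se <- stats::setNames(sqrt(pmax(diag(Vc), 0)), names(comp0))
  fit
}

#' Best linear unbiased predictors of random effects
#'
#' Returns the predicted genetic deviations (or other random-term effects)
#' per individual and trait from a converged fit. Individuals without
#' phenotypes can be predicted through the pedigree by supplying the full
#' relationship matrix.
#'
#' @param fit a `qg_fit`.
#' @param term which random term to predict (default `"genetic"`).
#' @param A optional full relationship matrix including unphenotyped
#'   relatives; their predictions are obtained by regression through A.
#' @return data frame with columns `id`, `trait`, `blup`.
#' @export
blup <- function(fit, term = "genetic", A = NULL) {
  fr <- fit$frame
  info <- fit$par_info
  sc <- fit$scaffold
  if (!term %in% names(fr$terms)) stop("no random term '", term, "'")
  pi_ <- info[[paste0("term.", term)]]
  tm <- fr$terms[[term]]
  ts <- sc$term_slices[[term]]
  L <- .struct_load(pi_$struct, fr$t, fit$par[pi_$idx])
  s <- fit$solution_env$s
  Fhat <- matrix(s[ts$col0 + seq_len(tm$m * tm$q)], tm$q, tm$m)
  Uhat <- Fhat %*% t(L)  # q x t, scaled units
  Uhat <- sweep(Uhat, 2, fr$sds, `*`)
  out <- data.frame(id = rep(tm$labels, fr$t),
                    trait = rep(fr$traits, each = tm$q),
                    blup = as.numeric(Uhat))
  if (!is.null(A) && term == "genetic") {
    extra <- setdiff(rownames(A), tm$labels)
    if (length(extra) > 0) {
      A_oo <- A[tm$labels, tm$labels]
      A_uo <- A[extra, tm$labels, drop = FALSE]
      proj <- A_uo %*% solve(A_oo)
      Uext <- proj %*% Uhat
      out <- rbind(out, data.frame(id = rep(extra, fr$t),
                                   trait = rep(fr$traits, each = length(extra)),
                                   blup = as.numeric(Uext)))
    }
  }
  out
}

#' Simulate a new response vector from a fitted model
#'
#' Draws fixed effects plus fresh random effects and residuals from the
#' fitted parameter values, over the same design (individuals, pedigree,
#' groups, occasions). This is the data-level resampling step of the
#' parametric bootstrap.
#'
#' @param fit a `qg_fit`.
#' @param seed integer seed.
#' @return the model-frame data with a resimulated `value` column.
#' @export
simulate_response <- function(fit, seed = 1) {
  fr <- fit$frame
  info <- fit$par_info
  sc <- fit$scaffold
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)

  y <- as.numeric(fr$X %*% fit$solution_env$s[seq_len(fr$p)])
  for (nm in names(fr$terms)) {
    tm <- fr$terms[[nm]]
    pi_ <- info[[paste0("term.", nm)]]
    L <- .struct_load(pi_$struct, fr$t, fit$par[pi_$idx])
    Z <- matrix(stats::rnorm(tm$q * tm$m), tm$q, tm$m)
    Fsim <- if (is.null(tm$cholK)) Z else crossprod(tm$cholK, Z)
    Usim <- Fsim %*% t(L)  # q x t
    y <- y + Usim[cbind(tm$lev, fr$ti)]
  }
  ## residuals per res-group
  res <- .frame_resid(fr, info, fit$par)
  for (pp in seq_along(fr$patterns)) {
    P <- fr$patterns[[pp]]
    sub <- res[[P$block]]$R[P$pos, P$pos, drop = FALSE]
    ch <- chol(sub)
    E <- matrix(stats::rnorm(P$count * P$size), P$count, P$size) %*% ch
    y[P$obs] <- y[P$obs] + as.numeric(E)
  }
  d <- fr$data
  d$value <- y * fr$sds[fr$ti]
  d
}
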
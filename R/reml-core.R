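## Generic REML machinery for pedigree-structured multi-trait mixed models.
##
## Model: y = X beta + sum_k Z_k u_k + e, with each random term k having
## covariance Sigma_k (x) K_k across (trait, level), K_k the known level
## covariance (the additive relationship matrix A for the genetic term,
## identity otherwise). Terms are reparameterised through loading matrices:
## u_k = (Lambda_k (x) I) f_k with f_k ~ N(0, I (x) K_k), so the loadings sit
## in the design matrix and the prior precision of the working effects is
## constant across evaluations. Residuals are independent between
## "co-observation groups" (occasion x residual block) and carry an
## unstructured covariance within them.
##
## The restricted log-likelihood is evaluated through the mixed-model
## equations: -2 logL = (n - p) log(2*pi) + log|R| + sum_k m_k log|K_k|
##                      + log|C| + y' P y,
## with C the full MME coefficient matrix. Gradients are analytic.

## ---- model frame ----------------------------------------------------------

.qg_frame <- function(data, traits, fixed = ~1, A = NULL,
                      random = list(genetic = "us", pe = "us", group = "diag"),
                      residual_blocks = NULL, scale = TRUE,
                      id_col = "id", group_col = "group",
                      occasion_col = "occasion") {
  stopifnot(all(c(id_col, "trait", "value") %in% names(data)))
  d <- data[data$trait %in% traits & !is.na(data$value), , drop = FALSE]
  if (nrow(d) == 0) stop("no observations for the requested traits")
  t_n <- length(traits)
  ti <- match(d$trait, traits)
  n <- nrow(d)

  sds <- rep(1, t_n)
  if (scale) {
    sds <- vapply(seq_len(t_n), function(k) stats::sd(d$value[ti == k]),
                  numeric(1))
    sds[!is.finite(sds) | sds == 0] <- 1
  }
  y <- d$value / sds[ti]

  ## fixed-effect design, block-diagonal across traits
  if (inherits(fixed, "formula")) fixed <- stats::setNames(
    rep(list(fixed), t_n), traits)
  Xcols <- list()
  X <- NULL
  for (k in seq_len(t_n)) {
    rows <- which(ti == k)
    mm <- stats::model.matrix(fixed[[traits[k]]], d[rows, , drop = FALSE])
    if (nrow(mm) != length(rows)) {
      stop("missing covariate values for trait ", traits[k])
    }
    qr_mm <- qr(mm)
    keep <- qr_mm$pivot[seq_len(qr_mm$rank)]
    dropped <- colnames(mm)[setdiff(seq_len(ncol(mm)), keep)]
    if (length(dropped) > 0) {
      message("dropping aliased fixed-effect column(s) for ", traits[k], ": ",
              paste(dropped, collapse = ", "))
    }
    mm <- mm[, sort(keep), drop = FALSE]
    blk <- matrix(0, n, ncol(mm))
    blk[rows, ] <- mm
    colnames(blk) <- paste0(traits[k], ":", colnames(mm))
    Xcols[[k]] <- blk
  }
  X <- do.call(cbind, Xcols)
  p <- ncol(X)
  x_trait <- rep(seq_len(t_n), vapply(Xcols, ncol, integer(1)))

  ## random terms
  ids <- unique(as.character(d[[id_col]]))
  id_idx <- match(as.character(d[[id_col]]), ids)
  terms <- list()
  for (nm in names(random)) {
    if (is.null(random[[nm]])) next
    struct <- random[[nm]]
    if (nm %in% c("genetic", "pe")) {
      lev <- id_idx
      q <- length(ids)
      labels <- ids
    } else if (nm == "group") {
      if (!group_col %in% names(d)) stop("no '", group_col, "' column")
      labels <- unique(as.character(d[[group_col]]))
      lev <- match(as.character(d[[group_col]]), labels)
      q <- length(labels)
    } else stop("unknown random term: ", nm)
    Kinv <- NULL
    logdetK <- 0
    cholK <- NULL
    if (nm == "genetic" && !is.null(A)) {
      if (!all(ids %in% rownames(A))) {
        stop("individuals missing from the relationship matrix: ",
             paste(utils::head(setdiff(ids, rownames(A))), collapse = ", "))
      }
      Asub <- A[ids, ids, drop = FALSE]
      chA <- chol(Asub)
      Kinv <- chol2inv(chA)
      logdetK <- 2 * sum(log(diag(chA)))
      cholK <- chA
    }
    m <- .struct_nfac(struct, t_n)
    terms[[nm]] <- list(name = nm, struct = struct, lev = lev, q = q, m = m,
                        labels = labels, Kinv = Kinv, logdetK = logdetK,
                        cholK = cholK, npar = .struct_npar(struct, t_n))
  }

  ## residual blocks (trait indices); default: independent traits
  if (is.null(residual_blocks)) {
    blocks <- as.list(seq_len(t_n))
  } else {
    blocks <- lapply(residual_blocks, function(b) {
      idx <- match(b, traits)
      if (anyNA(idx)) stop("residual block names unknown: ",
                           paste(b[is.na(idx)], collapse = ", "))
      sort(idx)
    })
    left <- setdiff(seq_len(t_n), unlist(blocks))
    blocks <- c(blocks, as.list(left))
  }
  if (anyDuplicated(unlist(blocks))) stop("residual blocks overlap")
  trait_block <- integer(t_n)
  trait_pos <- integer(t_n)
  for (b in seq_along(blocks)) {
    trait_block[blocks[[b]]] <- b
    trait_pos[blocks[[b]]] <- seq_along(blocks[[b]])
  }

  ## co-observation groups: occasion x block
  occ <- if (occasion_col %in% names(d)) {
    as.integer(factor(d[[occasion_col]]))
  } else seq_len(n)
  rg_key <- paste(occ, trait_block[ti])
  rg <- as.integer(factor(rg_key, levels = unique(rg_key)))

  ## pattern per res-group: block + positions present
  ord <- order(rg, trait_pos[ti])
  obs_by_rg <- split(ord, rg[ord])
  pat_key <- vapply(obs_by_rg, function(o) {
    paste(trait_block[ti[o[1]]], paste(trait_pos[ti[o]], collapse = ","))
  }, character(1))
  if (any(vapply(obs_by_rg, function(o) anyDuplicated(ti[o]) > 0,
                 logical(1)))) {
    stop("an occasion observes the same trait twice")
  }
  pat_levels <- unique(pat_key)
  pat_id <- match(pat_key, pat_levels)
  patterns <- lapply(seq_along(pat_levels), function(pp) {
    members <- which(pat_id == pp)
    o1 <- obs_by_rg[[members[1]]]
    size <- length(o1)
    obs_mat <- t(vapply(obs_by_rg[members], function(o) o,
                        integer(size)))
    if (size == 1) obs_mat <- matrix(unlist(obs_by_rg[members]), ncol = 1)
    list(block = trait_block[ti[o1[1]]], pos = trait_pos[ti[o1]],
         size = size, count = length(members), obs = obs_mat)
  })

  ## sparse R-inverse scaffold: within-res-group ordered pairs
  ri <- rj <- pa <- pb <- pp_ <- integer(0)
  for (pp in seq_along(patterns)) {
    P <- patterns[[pp]]
    s <- P$size
    for (a in seq_len(s)) for (b in seq_len(s)) {
      ri <- c(ri, P$obs[, a])
      rj <- c(rj, P$obs[, b])
      pa <- c(pa, rep(a, P$count))
      pb <- c(pb, rep(b, P$count))
      pp_ <- c(pp_, rep(pp, P$count))
    }
  }

  list(n = n, p = p, t = t_n, traits = traits, sds = sds, y = y,
       X = X, x_trait = x_trait, ti = ti, ids = ids, id_idx = id_idx,
       terms = terms, blocks = blocks, trait_block = trait_block,
       trait_pos = trait_pos, patterns = patterns,
       rpairs = list(i = ri, j = rj, a = pa, b = pb, pat = pp_),
       data = d, id_col = id_col, group_col = group_col, fixed = fixed)
}

## ---- parameter packing ----------------------------------------------------

.frame_par_info <- function(fr) {
  info <- list()
  off <- 0L
  for (nm in names(fr$terms)) {
    np <- fr$terms[[nm]]$npar
    info[[paste0("term.", nm)]] <- list(kind = "term", name = nm,
                                        struct = fr$terms[[nm]]$struct,
                                        t = fr$t, idx = off + seq_len(np))
    off <- off + np
  }
  for (b in seq_along(fr$blocks)) {
    tb <- length(fr$blocks[[b]])
    np <- tb * (tb + 1L) / 2L
    info[[paste0("res.", b)]] <- list(kind = "res", block = b, struct = "us",
                                      t = tb, idx = off + seq_len(np))
    off <- off + np
  }
  attr(info, "npar") <- off
  info
}

.frame_start <- function(fr, shares = NULL) {
  ## moment-based: phenotypic variance on the scaled data is ~1 per trait
  nterm <- length(fr$terms)
  if (is.null(shares)) {
    shares <- stats::setNames(rep(0.5 / max(nterm, 1), nterm), names(fr$terms))
  }
  par <- numeric(0)
  for (nm in names(fr$terms)) {
    par <- c(par, .struct_start(fr$terms[[nm]]$struct, fr$t, shares[[nm]]))
  }
  res_share <- max(1 - sum(unlist(shares)), 0.2)
  for (b in seq_along(fr$blocks)) {
    tb <- length(fr$blocks[[b]])
    par <- c(par, .struct_start("us", tb, res_share))
  }
  par
}

.frame_lower <- function(fr) {
  lo <- numeric(0)
  for (nm in names(fr$terms)) {
    lo <- c(lo, .struct_lower(fr$terms[[nm]]$struct, fr$t))
  }
  for (b in seq_along(fr$blocks)) {
    lo <- c(lo, .struct_lower("us", length(fr$blocks[[b]])))
  }
  lo
}

## ---- evaluation -----------------------------------------------------------

## builds the triplet scaffold of M = [X | W_1 | ... | W_K] once
.frame_scaffold <- function(fr) {
  n <- fr$n
  ## X entries: every column belonging to the observation's own trait is
  ## kept (zeros included) so that each observation of a given trait has the
  ## same number of stored entries -- the residual gradient relies on it
  xl_i <- xl_j <- integer(0)
  for (k in seq_len(fr$t)) {
    rows <- which(fr$ti == k)
    cols <- which(fr$x_trait == k)
    xl_i <- c(xl_i, rep(rows, times = length(cols)))
    xl_j <- c(xl_j, rep(cols, each = length(rows)))
  }
  trip_i <- xl_i
  trip_j <- xl_j
  xv <- fr$X[cbind(xl_i, xl_j)]
  off <- fr$p
  term_slices <- list()
  ti_e <- f_e <- integer(0)
  for (nm in names(fr$terms)) {
    tm <- fr$terms[[nm]]
    i_k <- rep(seq_len(n), tm$m)
    f_k <- rep(seq_len(tm$m), each = n)
    j_k <- off + (f_k - 1L) * tm$q + tm$lev[i_k]
    sl <- length(trip_i) + seq_along(i_k)
    term_slices[[nm]] <- list(slice = sl, ti = fr$ti[i_k], f = f_k,
                              lev = tm$lev[i_k], obs = i_k,
                              col0 = off, q = tm$q, m = tm$m)
    trip_i <- c(trip_i, i_k)
    trip_j <- c(trip_j, j_k)
    off <- off + tm$m * tm$q
  }
  D <- off
  ## CSR view of the scaffold (row-sorted entry order) for the residual
  ## gradient; per-evaluation values are reordered with `csr_ord`
  csr_ord <- order(trip_i)
  row_ptr <- c(0L, cumsum(tabulate(trip_i, nbins = n)))
  list(trip_i = trip_i, trip_j = trip_j, x_vals = xv,
       n_x = length(xv), term_slices = term_slices, D = D,
       csr_ord = csr_ord, csr_j = trip_j[csr_ord], row_ptr = row_ptr)
}

## residual matrices per block from parameters
.frame_resid <- function(fr, info, par) {
  lapply(seq_along(fr$blocks), function(b) {
    pi_ <- info[[paste0("res.", b)]]
    L <- .struct_load("us", pi_$t, par[pi_$idx])
    list(L = L, R = tcrossprod(L))
  })
}

## full evaluation: returns -2 * restricted logL and caches the pieces the
## gradient needs in `env`
.gen_eval <- function(par, fr, sc, info, env = NULL) {
  n <- fr$n
  D <- sc$D

  ## loadings
  lam <- list()
  vals <- sc$x_vals
  for (nm in names(fr$terms)) {
    pi_ <- info[[paste0("term.", nm)]]
    L <- .struct_load(pi_$struct, fr$t, par[pi_$idx])
    lam[[nm]] <- L
    ts <- sc$term_slices[[nm]]
    vals <- c(vals, L[cbind(ts$ti, ts$f)])
  }
  M <- Matrix::sparseMatrix(i = sc$trip_i, j = sc$trip_j, x = vals,
                            dims = c(n, D))

  ## residual blocks and sparse R-inverse
  res <- .frame_resid(fr, info, par)
  pat_inv <- vector("list", length(fr$patterns))
  logdetR <- 0
  for (pp in seq_along(fr$patterns)) {
    P <- fr$patterns[[pp]]
    sub <- res[[P$block]]$R[P$pos, P$pos, drop = FALSE]
    ch <- tryCatch(chol(sub), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    pat_inv[[pp]] <- chol2inv(ch)
    logdetR <- logdetR + P$count * 2 * sum(log(diag(ch)))
  }
  rv <- numeric(length(fr$rpairs$i))
  for (pp in seq_along(fr$patterns)) {
    sel <- fr$rpairs$pat == pp
    rv[sel] <- pat_inv[[pp]][cbind(fr$rpairs$a[sel], fr$rpairs$b[sel])]
  }
  Rinv <- Matrix::sparseMatrix(i = fr$rpairs$i, j = fr$rpairs$j, x = rv,
                               dims = c(n, n))

  RinvM <- Rinv %*% M
  C <- as.matrix(Matrix::crossprod(M, RinvM))
  ## constant prior precision I (x) Kinv on the working effects
  logdetK <- 0
  for (nm in names(fr$terms)) {
    tm <- fr$terms[[nm]]
    ts <- sc$term_slices[[nm]]
    logdetK <- logdetK + tm$m * tm$logdetK
    for (f in seq_len(tm$m)) {
      cols <- ts$col0 + (f - 1L) * tm$q + seq_len(tm$q)
      if (is.null(tm$Kinv)) {
        dg <- cbind(cols, cols)
        C[dg] <- C[dg] + 1
      } else {
        C[cols, cols] <- C[cols, cols] + tm$Kinv
      }
    }
  }

  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logdetC <- 2 * sum(log(diag(ch)))
  Rinvy <- as.numeric(Rinv %*% fr$y)
  r <- as.numeric(Matrix::crossprod(M, Rinvy))
  s <- backsolve(ch, backsolve(ch, r, transpose = TRUE))
  quad <- sum(fr$y * Rinvy) - sum(r * s)

  m2l <- (n - fr$p) * log(2 * pi) + logdetR + logdetK + logdetC + quad
  if (!is.finite(m2l)) return(1e10)
  if (!is.null(env)) {
    env$par <- par
    env$lam <- lam
    env$res <- res
    env$pat_inv <- pat_inv
    env$M <- M
    env$vals <- vals
    env$Rinv <- Rinv
    env$RinvM <- RinvM
    env$chC <- ch
    env$s <- s
    env$m2l <- m2l
  }
  m2l
}

## analytic gradient of -2 logL; requires a cache from .gen_eval
.gen_grad <- function(par, fr, sc, info, env) {
  if (is.null(env$par) || !identical(env$par, par)) {
    v <- .gen_eval(par, fr, sc, info, env)
    if (v >= 1e10) return(rep(0, length(par)))  # flat in a failed region
  }
  n <- fr$n
  D <- sc$D
  Cinv <- chol2inv(env$chC)
  s <- env$s
  ehat <- fr$y - as.numeric(env$M %*% s)
  h <- as.numeric(env$Rinv %*% ehat)

  g <- numeric(length(par))

  ## --- loading parameters ---
  RM <- methods::as(env$RinvM, "TsparseMatrix")
  rm_o <- RM@i + 1L
  rm_j <- RM@j + 1L
  rm_v <- RM@x
  for (nm in names(fr$terms)) {
    pi_ <- info[[paste0("term.", nm)]]
    ts <- sc$term_slices[[nm]]
    tm <- fr$terms[[nm]]
    Smat <- matrix(s[ts$col0 + seq_len(tm$m * tm$q)], tm$q, tm$m)
    dLam <- matrix(0, fr$t, tm$m)
    for (f in seq_len(tm$m)) {
      ## quadratic part: -2 sum_{o: trait=t} S[lev_o, f] h_o
      contrib_q <- Smat[tm$lev, f] * h
      ## log|C| part: 2 * sum_{o: trait=t} (RinvM %*% Cinv)[o, col(f, lev_o)]
      colv <- ts$col0 + (f - 1L) * tm$q + tm$lev[rm_o]
      bv <- rm_v * Cinv[rm_j + D * (colv - 1L)]
      contrib_c <- rowsum(bv, fr$ti[rm_o])
      agg_q <- rowsum(contrib_q, fr$ti)
      tr_rows <- as.integer(rownames(agg_q))
      dLam[tr_rows, f] <- dLam[tr_rows, f] - 2 * agg_q
      tr_rows_c <- as.integer(rownames(contrib_c))
      dLam[tr_rows_c, f] <- dLam[tr_rows_c, f] + 2 * contrib_c
    }
    g[pi_$idx] <- .struct_grad(pi_$struct, fr$t, par[pi_$idx],
                               env$lam[[nm]], dLam)
  }

  ## --- residual parameters ---
  ## M rows in CSR form (from the scaffold, so every observation of a trait
  ## has the same entry count) for the Psi products
  m_j <- sc$csr_j
  m_v <- env$vals[sc$csr_ord]
  row_ptr <- sc$row_ptr

  for (b in seq_along(fr$blocks)) {
    pi_ <- info[[paste0("res.", b)]]
    tb <- pi_$t
    dR_acc <- matrix(0, tb, tb)  # gradient wrt entries of R_b (symmetric)
    for (pp in seq_along(fr$patterns)) {
      P <- fr$patterns[[pp]]
      if (P$block != b) next
      sz <- P$size
      Rinv_p <- env$pat_inv[[pp]]
      ## H = sum over occasions of h h'
      hm <- matrix(h[P$obs], P$count, sz)
      H <- crossprod(hm)
      ## Psi_agg[a, b'] = sum_occ M[o_a,] Cinv M[o_b',]'
      Psi <- matrix(0, sz, sz)
      for (a in seq_len(sz)) for (bb in seq_len(sz)) {
        oa <- P$obs[, a]
        ob <- P$obs[, bb]
        na_ <- row_ptr[oa[1] + 1L] - row_ptr[oa[1]]
        nb_ <- row_ptr[ob[1] + 1L] - row_ptr[ob[1]]
        Ja <- matrix(m_j[rep(row_ptr[oa], each = na_) + seq_len(na_)],
                     ncol = na_, byrow = TRUE)
        Va <- matrix(m_v[rep(row_ptr[oa], each = na_) + seq_len(na_)],
                     ncol = na_, byrow = TRUE)
        Jb <- matrix(m_j[rep(row_ptr[ob], each = nb_) + seq_len(nb_)],
                     ncol = nb_, byrow = TRUE)
        Vb <- matrix(m_v[rep(row_ptr[ob], each = nb_) + seq_len(nb_)],
                     ncol = nb_, byrow = TRUE)
        acc <- 0
        for (u in seq_len(na_)) {
          for (v in seq_len(nb_)) {
            acc <- acc + sum(Va[, u] * Vb[, v] *
                               Cinv[Ja[, u] + D * (Jb[, v] - 1L)])
          }
        }
        Psi[a, bb] <- acc
      }
      Phi <- Rinv_p %*% Psi %*% Rinv_p
      ## d(-2l)/dR_sub = count * Rinv_p - Phi - H  (trace pairing)
      Gsub <- P$count * Rinv_p - Phi - H
      ## scatter into the block's trait positions
      dR_acc[P$pos, P$pos] <- dR_acc[P$pos, P$pos] + Gsub
    }
    ## chain to Cholesky parameters: dR = E Lr' + Lr E'
    Lr <- env$res[[b]]$L
    dLr <- 2 * dR_acc %*% Lr
    g[pi_$idx] <- .struct_grad("us", tb, par[pi_$idx], Lr, dLr)
  }
  g
}
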
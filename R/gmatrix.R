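#' Genetic correlations from a genetic covariance matrix
#'
#' `r_a(x,y) = cov_a(x,y) / sqrt(Va(x) * Va(y))`. Traits with zero (or
#' negative, at the numerical boundary) genetic variance get `NA`
#' correlations rather than fabricated values.
#'
#' @param G symmetric additive genetic covariance matrix.
#' @return correlation matrix with unit diagonal (`NA` rows/columns for
#'   zero-variance traits).
#' @examples
#' genetic_correlations(guppy_g_matrix())["rel_area", "time_in_middle"]
#' @export
genetic_correlations <- function(G) {
  G <- .check_symmetric(G)
  v <- diag(G)
  ok <- v > 0
  R <- matrix(NA_real_, nrow(G), ncol(G), dimnames = dimnames(G))
  if (any(ok)) {
    d <- 1 / sqrt(v[ok])
    R[ok, ok] <- G[ok, ok, drop = FALSE] * tcrossprod(d)
  }
  diag(R)[ok] <- 1
  R
}

.check_symmetric <- function(G, tol = 1e-8) {
  G <- as.matrix(G)
  if (nrow(G) != ncol(G)) stop("matrix is not square")
  if (max(abs(G - t(G))) > tol * max(1, max(abs(G)))) {
    stop("matrix is not symmetric")
  }
  (G + t(G)) / 2
}

#' Eigen decomposition of G (major axis g-max)
#'
#' Eigenvalues are returned in descending order with the proportion of total
#' genetic variance captured by each axis; small negative eigenvalues
#' (numerical boundary estimates) are reported raw but clipped to zero for
#' the proportion accounting. Each eigenvector is oriented so that its
#' largest-magnitude loading is positive.
#'
#' @param G symmetric genetic covariance matrix.
#' @return object of class `qg_eigen`: `values`, `proportions`, `vectors`
#'   (columns are axes; the first is g-max), `traits`.
#' @examples
#' es <- eigen_decomposition(guppy_g_matrix())
#' round(100 * es$proportions[1:2], 1)  # ~59.4 and 20.3
#' @export
eigen_decomposition <- function(G) {
  G <- .check_symmetric(G)
  eg <- eigen(G, symmetric = TRUE)
  vals <- eg$values
  if (min(vals) < -1e-8 * max(abs(vals), 1)) {
    warning("G has a clearly negative eigenvalue (", format(min(vals)),
            "); it is reported raw and ignored in the proportions")
  }
  vecs <- eg$vectors
  for (j in seq_len(ncol(vecs))) {
    k <- which.max(abs(vecs[, j]))
    if (vecs[k, j] < 0) vecs[, j] <- -vecs[, j]
  }
  pos <- pmax(vals, 0)
  props <- if (sum(pos) > 0) pos / sum(pos) else rep(NA_real_, length(vals))
  rownames(vecs) <- rownames(G)
  colnames(vecs) <- paste0("PC", seq_along(vals))
  structure(list(values = vals, proportions = props, vectors = vecs,
                 traits = rownames(G)), class = "qg_eigen")
}

#' @export
print.qg_eigen <- function(x, ...) {
  cat("eigen decomposition of G\n")
  print(data.frame(axis = paste0("PC", seq_along(x$values)),
                   eigenvalue = round(x$values, 4),
                   pct_variance = round(100 * x$proportions, 1)))
  invisible(x)
}

#' Parametric bootstrap of a fitted model's G matrix
#'
#' For each replicate, a complete response vector is simulated from the
#' fitted model (fixed effects plus fresh genetic, permanent-environment,
#' group and residual draws over the same pedigree and design), the model is
#' refitted (warm-started from the point estimate), and the replicate
#' genetic covariance matrix is stored. Replicates that fail to converge are
#' flagged and excluded from interval computation, never silently dropped.
#'
#' @param fit a `qg_fit` with a genetic term.
#' @param n_reps number of bootstrap replicates.
#' @param seed integer seed; replicate `r` uses `seed + r`.
#' @param se_warn warn if more than 20% of replicates fail.
#' @return object of class `qg_boot`: list of `G` matrices, `converged`
#'   logical vector, `seed`.
#' @export
parametric_bootstrap <- function(fit, n_reps = 200, seed = 1,
                                 se_warn = TRUE) {
  if (!"genetic" %in% names(fit$frame$terms)) {
    stop("fit has no genetic term to bootstrap")
  }
  args <- .refit_args(fit)
  Gs <- vector("list", n_reps)
  ok <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    d <- simulate_response(fit, seed = seed + r)
    rf <- tryCatch(
      do.call(reml_fit, c(list(data = d), args, list(start = fit$par))),
      error = function(e) NULL)
    if (!is.null(rf) && is.finite(rf$logLik)) {
      Gs[[r]] <- rf$components$genetic
      ok[r] <- rf$convergence == 0
    }
  }
  n_fail <- sum(!ok)
  if (se_warn && n_fail > 0.2 * n_reps) {
    warning(n_fail, " of ", n_reps, " bootstrap replicates failed to converge")
  }
  structure(list(G = Gs, converged = ok, n_reps = n_reps, seed = seed),
            class = "qg_boot")
}

## reconstruct reml_fit arguments from a stored fit
.refit_args <- function(fit) {
  fr <- fit$frame
  random <- lapply(fr$terms, function(tm) tm$struct)
  A <- NULL
  if ("genetic" %in% names(fr$terms) && !is.null(fr$terms$genetic$cholK)) {
    A <- crossprod(fr$terms$genetic$cholK)
    dimnames(A) <- list(fr$ids, fr$ids)
  }
  blocks <- lapply(fr$blocks, function(b) fr$traits[b])
  blocks <- blocks[lengths(blocks) > 1]
  list(traits = fr$traits, fixed = fr$fixed, A = A,
       random = random,
       residual_blocks = if (length(blocks)) blocks else NULL,
       scale = TRUE, engine = fit$engine, control = fit$control)
}

#' @export
print.qg_boot <- function(x, ...) {
  cat("parametric bootstrap:", x$n_reps, "replicates,",
      sum(x$converged), "converged\n")
  invisible(x)
}

#' Bootstrap confidence intervals on eigen structure
#'
#' Eigen-decomposes every usable bootstrap replicate of G, aligns each
#' eigenvector to the reference decomposition by sign (flip when the dot
#' product with the reference axis is negative; axes are matched by rank),
#' and attaches 2.5/97.5 percentile intervals to the reference loadings and
#' variance proportions. A loading is flagged significant when its interval
#' excludes zero.
#'
#' @param boot a `qg_boot`.
#' @param reference a `qg_eigen` for the point estimate of G.
#' @param level interval coverage (default 0.95).
#' @return the reference `qg_eigen` with added elements
#'   `loading_lo`/`loading_hi` (matrices), `prop_lo`/`prop_hi`,
#'   `significant` (logical matrix) and `n_used`.
#' @export
loading_intervals <- function(boot, reference, level = 0.95) {
  use <- which(boot$converged & !vapply(boot$G, is.null, logical(1)))
  if (length(use) < 2) stop("need at least two usable bootstrap replicates")
  t_n <- length(reference$values)
  al <- (1 - level) / 2
  load_arr <- array(NA_real_, dim = c(t_n, t_n, length(use)))
  prop_arr <- matrix(NA_real_, t_n, length(use))
  for (k in seq_along(use)) {
    er <- eigen_decomposition(boot$G[[use[k]]])
    V <- er$vectors
    for (j in seq_len(t_n)) {
      if (sum(V[, j] * reference$vectors[, j]) < 0) V[, j] <- -V[, j]
    }
    load_arr[, , k] <- V
    prop_arr[, k] <- er$proportions
  }
  qlo <- apply(load_arr, c(1, 2), stats::quantile, probs = al, names = FALSE)
  qhi <- apply(load_arr, c(1, 2), stats::quantile, probs = 1 - al,
               names = FALSE)
  dimnames(qlo) <- dimnames(qhi) <- dimnames(reference$vectors)
  reference$loading_lo <- qlo
  reference$loading_hi <- qhi
  reference$prop_lo <- apply(prop_arr, 1, stats::quantile, probs = al,
                             na.rm = TRUE)
  reference$prop_hi <- apply(prop_arr, 1, stats::quantile, probs = 1 - al,
                             na.rm = TRUE)
  reference$significant <- qlo > 0 | qhi < 0
  reference$n_used <- length(use)
  reference
}

#' Bivariate genetic confidence ellipse
#'
#' Boundary of the region expected to contain `coverage` of a bivariate
#' normal distribution with covariance `G2`:
#' `x' G2^{-1} x = qchisq(coverage, 2)`. Points are returned counter-
#' clockwise starting from the major axis. A numerically singular `G2`
#' yields the degenerate segment along the dominant axis, flagged with
#' attribute `degenerate`.
#'
#' @param G2 2 x 2 symmetric covariance matrix.
#' @param coverage probability mass inside the ellipse.
#' @param n_points number of boundary points.
#' @return matrix with columns `x`, `y` (and attribute `degenerate`).
#' @export
confidence_ellipse <- function(G2, coverage = 0.95, n_points = 256) {
  G2 <- .check_symmetric(G2)
  stopifnot(nrow(G2) == 2, coverage > 0, coverage < 1)
  eg <- eigen(G2, symmetric = TRUE)
  if (min(eg$values) < -1e-10 * max(abs(eg$values), 1)) {
    stop("G2 is not positive semi-definite")
  }
  vals <- pmax(eg$values, 0)
  degenerate <- vals[2] <= 1e-12 * max(vals[1], 1)
  r <- sqrt(stats::qchisq(coverage, df = 2))
  theta <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  circ <- rbind(cos(theta), sin(theta)) * r
  pts <- t(eg$vectors %*% (circ * sqrt(vals)))
  colnames(pts) <- c("x", "y")
  attr(pts, "degenerate") <- degenerate
  pts
}
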
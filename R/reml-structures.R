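## Covariance-structure parameterisations for random terms and residual
## blocks. Every trait x trait covariance matrix is represented through a
## loading matrix Lambda (t x m): Sigma = Lambda %*% t(Lambda). Positive
## (semi-)definiteness is therefore structural, and rank-deficient structures
## (a cross-context genetic correlation fixed at +1, say) need no boundary
## handling by the optimiser.
##
##   us     : full covariance; Lambda is lower-triangular Cholesky, diagonal
##            on log scale, m = t, t(t+1)/2 parameters
##   diag   : independent traits; Lambda diagonal with log-sd parameters
##   rank1  : single common factor with free loadings (correlations +-1)
##   shared : single common factor with one shared loading (equal variances,
##            correlation +1)

.struct_npar <- function(struct, t) {
  switch(struct,
         us = t * (t + 1L) / 2L,
         diag = t,
         rank1 = t,
         shared = 1L,
         stop("unknown covariance structure: ", struct))
}

.struct_nfac <- function(struct, t) {
  switch(struct, us = t, diag = t, rank1 = 1L, shared = 1L)
}

## t x m loading matrix from the unconstrained parameter vector
.struct_load <- function(struct, t, par) {
  switch(struct,
         us = {
           L <- matrix(0, t, t)
           L[lower.tri(L, diag = TRUE)] <- par
           diag(L) <- exp(diag(L))
           L
         },
         diag = diag(exp(par), t, t),
         rank1 = matrix(par, t, 1),
         shared = matrix(rep(par, t), t, 1))
}

## gradient wrt par from gradient wrt Lambda entries (t x m matrix dLam)
.struct_grad <- function(struct, t, par, L, dLam) {
  switch(struct,
         us = {
           g <- dLam[lower.tri(dLam, diag = TRUE)]
           ## log-scale diagonal: d Lambda_ii / d par = Lambda_ii
           vech_idx <- matrix(0L, t, t)
           vech_idx[lower.tri(vech_idx, diag = TRUE)] <- seq_along(par)
           dd <- diag(vech_idx)
           g[dd] <- g[dd] * diag(L)
           g
         },
         diag = diag(dLam) * diag(L),
         rank1 = as.numeric(dLam),
         shared = sum(dLam))
}

## implied covariance matrix
.struct_sigma <- function(L) tcrossprod(L)

## default starting parameters putting variance `v` (per trait) on the
## diagonal with no covariance
.struct_start <- function(struct, t, v) {
  sd_log <- 0.5 * log(v)
  switch(struct,
         us = {
           par <- numeric(t * (t + 1L) / 2L)
           vech_idx <- matrix(0L, t, t)
           vech_idx[lower.tri(vech_idx, diag = TRUE)] <- seq_along(par)
           par[diag(vech_idx)] <- sd_log
           par
         },
         diag = rep(sd_log, t),
         rank1 = rep(sqrt(v), t),
         shared = sqrt(v))
}

## lower bounds (only log-scale parameters are bounded, to keep standard
## deviations above ~2e-9 on the internally scaled data)
.struct_lower <- function(struct, t) {
  lo <- -8
  switch(struct,
         us = {
           par <- rep(-Inf, t * (t + 1L) / 2L)
           vech_idx <- matrix(0L, t, t)
           vech_idx[lower.tri(vech_idx, diag = TRUE)] <- seq_along(par)
           par[diag(vech_idx)] <- lo
           par
         },
         diag = rep(lo, t),
         rank1 = rep(-Inf, t),
         shared = -Inf)
}
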
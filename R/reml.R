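# Restricted-likelihood machinery shared by the merit, kernel-variance,
# association and prediction stages. Three engines:
#   * reml_eigen_2vc : closed-form 1-D REML for one kernel + residual,
#     via a single eigendecomposition (used by SNP-BLUP, GBLUP, MLM null).
#   * reml_em_mme    : EM-REML on Henderson's mixed-model equations for
#     design-matrix random terms with heteroscedastic observation weights
#     (used by the merit stage).
#   * reml_em_kernels: EM-REML on the phenotypic covariance for an
#     arbitrary set of dense kernels + residual (used by the G2A model).
# All three report the restricted log-likelihood with the same constant,
#   -2ll = (n-p) log 2pi + log|V| + log|X'V^-1 X| + y'Py,
# so likelihood ratios across engines/models are comparable.

# Profiled REML for V = s2 * (h * d + (1 - h)) given the rotated data.
# yt, Xt: y and X premultiplied by the eigenvector transpose; d: eigenvalues.
.reml_profile_h <- function(h, yt, Xt, d) {
  n <- length(yt); p <- ncol(Xt)
  v <- h * d + (1 - h)
  v[v < 1e-12] <- 1e-12
  XtV <- Xt / v
  A <- crossprod(XtV, Xt)
  b <- crossprod(XtV, yt)
  cA <- chol(A)
  q <- sum(yt^2 / v) - sum(backsolve(cA, b, transpose = TRUE)^2)
  s2 <- q / (n - p)
  m2ll <- (n - p) * (log(2 * pi) + 1 + log(s2)) + sum(log(v)) +
    2 * sum(log(diag(cA)))
  list(m2ll = m2ll, s2 = s2, v = v, A = A, b = b)
}

#' One-kernel REML via eigendecomposition
#'
#' Fits y = Xb + g + e with g ~ N(0, s2g * K), e ~ N(0, s2e * I) by
#' profiling the restricted likelihood over the heritability ratio
#' h = s2g / (s2g + s2e) on the eigenbasis of K.
#'
#' @param y Response vector.
#' @param K Symmetric PSD kernel (or a precomputed `eigen()` result).
#' @param X Fixed-effect design (default intercept only).
#' @return list with s2g, s2e, h, beta, blup (kernel-scale BLUP of g),
#'   loglik, eig.
#' @keywords internal
reml_eigen_2vc <- function(y, K, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  eig <- if (is.list(K) && !is.null(K$vectors)) K else eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  yt <- drop(crossprod(eig$vectors, y))
  Xt <- crossprod(eig$vectors, X)
  f <- function(h) .reml_profile_h(h, yt, Xt, d)$m2ll
  opt <- stats::optimize(f, c(1e-9, 1 - 1e-9), tol = 1e-10)
  h <- opt$minimum
  pr <- .reml_profile_h(h, yt, Xt, d)
  s2 <- pr$s2
  beta <- solve(pr$A, pr$b)
  r <- yt - Xt %*% beta
  # BLUP of g: s2g * K V^-1 (y - Xb); on the eigenbasis V^-1 is diagonal
  u <- h * d * (r / pr$v)
  blup <- drop(eig$vectors %*% u)
  list(s2g = s2 * h, s2e = s2 * (1 - h), h = h,
       beta = drop(beta), blup = blup,
       loglik = -0.5 * pr$m2ll, eig = eig)
}

#' EM-REML on the mixed-model equations
#'
#' Fits y = Xb + sum_k Z_k u_k + e with u_k ~ N(0, s2_k I) and
#' heteroscedastic residuals Var(e_i) = s2e / w_i. Weights are normalized
#' to mean 1 so s2e is an average residual variance. The EM iteration is
#' the classical Henderson form on the MME; it is monotone in the
#' restricted likelihood.
#'
#' @param y Response. @param X Fixed design (full column rank).
#' @param Zlist Named list of incidence matrices.
#' @param weights Positive observation weights (precision multipliers).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param maxit Maximum EM iterations.
#' @param floor Lower bound kept on each variance component.
#' @return list: sigma2 (named, incl. residual), beta, u (list), cinv_diag
#'   (list of PEV/s2e diagonals per term), loglik, iterations, converged.
#' @keywords internal
reml_em_mme <- function(y, X, Zlist, weights = NULL, tol = 1e-8,
                        maxit = 500L, floor = 1e-10) {
  n <- length(y)
  p <- ncol(X)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights <= 0)) stop("weights must be > 0")
  w <- as.numeric(weights) / mean(weights)
  qk <- vapply(Zlist, ncol, integer(1))
  K <- length(Zlist)
  TT <- cbind(X, do.call(cbind, Zlist))
  TW <- TT * w
  CtT <- crossprod(TW, TT)
  rhs <- drop(crossprod(TW, y))
  ywy <- sum(w * y^2)
  sumlogw <- sum(log(w))
  idx <- vector("list", K)
  off <- p
  for (k in seq_len(K)) {
    idx[[k]] <- off + seq_len(qk[k])
    off <- off + qk[k]
  }
  s2 <- c(rep(stats::var(y) / (K + 1), K), stats::var(y) / (K + 1))
  ll_old <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    lam <- s2[K + 1] / s2[seq_len(K)]
    C <- CtT
    for (k in seq_len(K)) {
      dg <- idx[[k]]
      C[cbind(dg, dg)] <- C[cbind(dg, dg)] + lam[k]
    }
    cC <- chol(C)
    theta <- backsolve(cC, backsolve(cC, rhs, transpose = TRUE))
    Cinv <- chol2inv(cC)
    s2e <- max(floor, (ywy - sum(theta * rhs)) / (n - p))
    ypy <- (ywy - sum(theta * rhs)) / s2e
    m2ll <- (n - p) * log(2 * pi) + n * log(s2e) - sumlogw +
      sum(qk * log(s2[seq_len(K)])) +
      (2 * sum(log(diag(cC))) - (p + sum(qk)) * log(s2e)) + ypy
    ll <- -0.5 * m2ll
    ll_trace[it] <- ll
    if (is.finite(ll_old) &&
        abs(ll - ll_old) / (abs(ll_old) + 1) < tol) {
      converged <- TRUE
    }
    s2_new <- s2
    for (k in seq_len(K)) {
      uk <- theta[idx[[k]]]
      trC <- sum(diag(Cinv)[idx[[k]]])
      s2_new[k] <- max(floor, (sum(uk^2) + s2e * trC) / qk[k])
    }
    s2_new[K + 1] <- s2e
    s2 <- s2_new
    ll_old <- ll
    if (converged || it >= maxit) break
  }
  u <- lapply(seq_len(K), function(k) {
    v <- theta[idx[[k]]]
    names(v) <- colnames(Zlist[[k]])
    v
  })
  names(u) <- names(Zlist)
  cinv_diag <- lapply(seq_len(K), function(k) diag(Cinv)[idx[[k]]])
  names(cinv_diag) <- names(Zlist)
  names(s2) <- c(names(Zlist), "residual")
  list(sigma2 = s2, beta = theta[seq_len(p)], u = u,
       cinv_diag = cinv_diag, loglik = ll_old, ll_trace = ll_trace,
       iterations = it, converged = converged)
}

#' EM-REML for dense kernel variance components
#'
#' Fits y = Xb + sum_k g_k + e with g_k ~ N(0, s2_k A_k) for arbitrary
#' symmetric PSD kernels A_k, by the monotone EM recursion
#' s2_k <- s2_k + (s2_k^2 / n) * (y'P A_k P y - tr(P A_k)).
#'
#' @param y Response. @param Klist Named list of kernels (residual term is
#'   implicit). @param X Fixed design.
#' @return list: sigma2 (named, incl. residual), proportions, beta, blup
#'   (list of component BLUPs), loglik, iterations, converged.
#' @keywords internal
reml_em_kernels <- function(y, Klist, X = NULL, tol = 1e-8,
                            maxit = 2000L, floor = 1e-10) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  p <- ncol(X)
  K <- length(Klist)
  vy <- stats::var(y)
  s2 <- rep(vy / (K + 1), K + 1)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  I_n <- diag(n)
  repeat {
    it <- it + 1L
    V <- s2[K + 1] * I_n
    for (k in seq_len(K)) V <- V + s2[k] * Klist[[k]]
    cV <- chol(V)
    Vinv <- chol2inv(cV)
    VX <- Vinv %*% X
    A <- crossprod(X, VX)
    cA <- chol(A)
    P <- Vinv - VX %*% chol2inv(cA) %*% t(VX)
    Py <- drop(P %*% y)
    m2ll <- (n - p) * log(2 * pi) + 2 * sum(log(diag(cV))) +
      2 * sum(log(diag(cA))) + sum(y * Py)
    ll <- -0.5 * m2ll
    if (is.finite(ll_old) && abs(ll - ll_old) / (abs(ll_old) + 1) < tol)
      converged <- TRUE
    for (k in seq_len(K)) {
      KPy <- Klist[[k]] %*% Py
      upd <- s2[k] + (s2[k]^2 / n) * (sum(Py * KPy) - sum(P * Klist[[k]]))
      s2[k] <- max(floor, upd)
    }
    upd <- s2[K + 1] + (s2[K + 1]^2 / n) * (sum(Py^2) - sum(diag(P)))
    s2[K + 1] <- max(floor, upd)
    ll_old <- ll
    if (converged || it >= maxit) break
  }
  # final solutions at the converged components
  V <- s2[K + 1] * I_n
  for (k in seq_len(K)) V <- V + s2[k] * Klist[[k]]
  Vinv <- chol2inv(chol(V))
  VX <- Vinv %*% X
  beta <- solve(crossprod(X, VX), crossprod(VX, y))
  r <- y - X %*% beta
  Vr <- Vinv %*% r
  blup <- lapply(seq_len(K), function(k) s2[k] * drop(Klist[[k]] %*% Vr))
  names(blup) <- names(Klist)
  names(s2) <- c(names(Klist), "residual")
  list(sigma2 = s2, proportions = s2 / sum(s2), beta = drop(beta),
       blup = blup, loglik = ll_old, iterations = it, converged = converged)
}
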
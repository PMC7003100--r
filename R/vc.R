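#' G2A variance decomposition
#'
#' Fits y = mu + psi + omega + eps with psi ~ N(0, K s2psi) (additive),
#' omega ~ N(0, Q s2omega) (additive-by-additive) and i.i.d. residuals,
#' by monotone EM-REML. With `groups`, the decomposition is run within
#' each family, rebuilding K and Q from that family's markers and
#' within-family allele frequencies (pooled kernels would leak
#' across-family structure into the within-family components).
#'
#' @param y Named vector of genetic values.
#' @param kernels A [build_kernels()] result (ignored when `groups` and
#'   `panel` are given and kernels are rebuilt per family).
#' @param groups Optional family id per individual (same order as y).
#' @param panel Required with `groups`: the [marker_panel()] to rebuild
#'   within-family kernels from.
#' @param min_group Families smaller than this are skipped with a warning.
#' @param tol,maxit EM controls (component floor 1e-10).
#' @return Object of class `g2a_fit`. Pooled: sigma2, proportions,
#'   loglik, converged. Grouped: `by_family` data.frame with one row per
#'   family (components, proportions, convergence).
#' @export
fit_g2a <- function(y, kernels = NULL, groups = NULL, panel = NULL,
                    min_group = 10L, tol = 1e-8, maxit = 2000L) {
  if (is.null(groups)) {
    if (is.null(kernels)) stop("supply kernels for a pooled fit")
    stopifnot(inherits(kernels, "kernel_set"))
    fit <- reml_em_kernels(y, list(additive = kernels$K,
                                   epistatic = kernels$Q),
                           tol = tol, maxit = maxit)
    return(structure(list(pooled = TRUE, sigma2 = fit$sigma2,
                          proportions = fit$proportions,
                          blup = fit$blup, loglik = fit$loglik,
                          iterations = fit$iterations,
                          converged = fit$converged),
                     class = "g2a_fit"))
  }
  if (is.null(panel)) stop("panel is required for a within-family fit")
  if (length(groups) != length(y)) stop("groups must align with y")
  rows <- vector("list", 0)
  for (f in unique(groups)) {
    i <- which(groups == f)
    if (length(i) < min_group) {
      warning("family ", f, " has ", length(i),
              " individuals (< ", min_group, "); skipped")
      next
    }
    geno <- panel$genotypes[match(names(y)[i], rownames(panel$genotypes)), ,
                            drop = FALSE]
    pf <- colMeans(geno) / 2
    poly <- pf > 0 & pf < 1
    if (sum(poly) < 2) {
      warning("family ", f, " has <2 segregating markers; skipped")
      next
    }
    Mf <- sweep(geno[, poly, drop = FALSE], 2, 2 * pf[poly])
    ks <- build_kernels(Mf)
    fit <- reml_em_kernels(y[i], list(additive = ks$K, epistatic = ks$Q),
                           tol = tol, maxit = maxit)
    rows[[length(rows) + 1L]] <- data.frame(
      family = f, n = length(i),
      s2_additive = fit$sigma2[["additive"]],
      s2_epistatic = fit$sigma2[["epistatic"]],
      s2_residual = fit$sigma2[["residual"]],
      prop_additive = fit$proportions[["additive"]],
      prop_epistatic = fit$proportions[["epistatic"]],
      prop_residual = fit$proportions[["residual"]],
      converged = fit$converged,
      stringsAsFactors = FALSE
    )
  }
  structure(list(pooled = FALSE, by_family = do.call(rbind, rows)),
            class = "g2a_fit")
}

#' @export
print.g2a_fit <- function(x, ...) {
  if (isTRUE(x$pooled)) {
    cat("G2A variance decomposition (pooled)\n")
    pr <- rbind(sigma2 = x$sigma2, proportion = x$proportions)
    print(round(pr, 4))
    cat(if (x$converged) "converged" else "NOT converged",
        "after", x$iterations, "EM iterations\n")
  } else {
    cat("G2A variance decomposition by family (",
        nrow(x$by_family), " families)\n", sep = "")
    print(utils::head(x$by_family, 10))
  }
  invisible(x)
}

#' Bivariate GBLUP: additive genetic correlation
#'
#' Fits the two-trait model y_t = mu_t + psi_t + eps_t with
#' psi ~ N(0, K (x) Sigma_psi) and diagonal residual covariance, by
#' EM-REML on the eigenbasis of K (each eigencomponent contributes an
#' independent 2x2 block, which keeps the iteration O(n)). Returns the
#' additive genetic correlation rho_psi = cov / sqrt(var_i var_j), and
#' the Pearson correlation of the two BLUP vectors (the "genetic
#' correlation" in the pipeline's reporting).
#'
#' @param y1,y2 Aligned trait vectors (two traits for pleiotropy, or one
#'   trait in two years for stability).
#' @param K Additive relationship matrix for the shared individuals.
#' @param constrain "none" (dense Sigma_psi) or "diag_psi" (independence
#'   constraint; reduces to two univariate GBLUP fits).
#' @param tol,maxit EM controls.
#' @return Object of class `bivariate_fit`: Sigma_psi, Sigma_eps,
#'   rho_psi, rho_blup, blup (n x 2), degenerate flag, loglik, converged.
#' @export
fit_bivariate <- function(y1, y2, K, constrain = c("none", "diag_psi"),
                          tol = 1e-8, maxit = 2000L) {
  constrain <- match.arg(constrain)
  n <- length(y1)
  if (length(y2) != n || nrow(K) != n)
    stop("y1, y2 and K must refer to the same individuals")
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  Y <- cbind(drop(crossprod(U, y1)), drop(crossprod(U, y2)))
  xo <- drop(crossprod(U, rep(1, n)))

  v1 <- stats::var(y1); v2 <- stats::var(y2)
  Sp <- diag(c(v1, v2)) / 2
  Se <- diag(c(v1, v2)) / 2
  eps_floor <- 1e-8 * c(v1, v2)
  pos <- d > 1e-10
  npos <- sum(pos)
  ll_old <- -Inf; converged <- FALSE; it <- 0L
  mu <- c(mean(y1), mean(y2))
  repeat {
    it <- it + 1L
    # per-block inverses of V_i = d_i * Sp + Se
    a <- d * Sp[1, 1] + Se[1, 1]
    b <- d * Sp[1, 2]
    cc <- d * Sp[2, 2] + Se[2, 2]
    det <- a * cc - b^2
    i11 <- cc / det; i22 <- a / det; i12 <- -b / det
    # GLS mean: X_i = xo_i * I2
    A11 <- sum(xo^2 * i11); A12 <- sum(xo^2 * i12); A22 <- sum(xo^2 * i22)
    b1 <- sum(xo * (i11 * Y[, 1] + i12 * Y[, 2]))
    b2 <- sum(xo * (i12 * Y[, 1] + i22 * Y[, 2]))
    Amat <- matrix(c(A11, A12, A12, A22), 2, 2)
    mu <- drop(solve(Amat, c(b1, b2)))
    R1 <- Y[, 1] - xo * mu[1]
    R2 <- Y[, 2] - xo * mu[2]
    # (Py)_i = Vinv_i r_i
    P1 <- i11 * R1 + i12 * R2
    P2 <- i12 * R1 + i22 * R2
    m2ll <- (2 * n - 2) * log(2 * pi) + sum(log(det)) +
      determinant(Amat, logarithm = TRUE)$modulus[1] +
      sum(R1 * P1 + R2 * P2)
    ll <- -0.5 * m2ll
    if (is.finite(ll_old) && abs(ll - ll_old) / (abs(ll_old) + 1) < tol)
      converged <- TRUE

    # E-step: psi_i = d_i Sp (Py)_i ; conditional covariance with the
    # REML correction Vinv X A^-1 X' Vinv added back
    Ainv <- solve(Amat)
    G1 <- d * (Sp[1, 1] * P1 + Sp[1, 2] * P2)
    G2 <- d * (Sp[1, 2] * P1 + Sp[2, 2] * P2)
    # accumulate M-step sums over d_i > 0
    # trace terms: sum_i (1/d_i)[ d_i Sp - d_i Sp (Vinv_i - corr_i) d_i Sp ]
    # where corr_i = Vinv_i X_i Ainv X_i' Vinv_i = xo_i^2 * Vinv_i Ainv Vinv_i
    dp <- d[pos]
    w11 <- i11[pos]; w12 <- i12[pos]; w22 <- i22[pos]
    xo2 <- xo[pos]^2
    # Vinv Ainv Vinv entries
    c11 <- w11 * (Ainv[1, 1] * w11 + Ainv[1, 2] * w12) +
      w12 * (Ainv[2, 1] * w11 + Ainv[2, 2] * w12)
    c12 <- w11 * (Ainv[1, 1] * w12 + Ainv[1, 2] * w22) +
      w12 * (Ainv[2, 1] * w12 + Ainv[2, 2] * w22)
    c22 <- w12 * (Ainv[1, 1] * w12 + Ainv[1, 2] * w22) +
      w22 * (Ainv[2, 1] * w12 + Ainv[2, 2] * w22)
    p11 <- w11 - xo2 * c11
    p12 <- w12 - xo2 * c12
    p22 <- w22 - xo2 * c22
    # Sp P Sp per block (2x2, symmetric)
    sp11 <- Sp[1, 1]; sp12 <- Sp[1, 2]; sp22 <- Sp[2, 2]
    q11 <- sp11 * (p11 * sp11 + p12 * sp12) + sp12 * (p12 * sp11 + p22 * sp12)
    q12 <- sp11 * (p11 * sp12 + p12 * sp22) + sp12 * (p12 * sp12 + p22 * sp22)
    q22 <- sp12 * (p11 * sp12 + p12 * sp22) + sp22 * (p12 * sp12 + p22 * sp22)
    S11 <- sum(G1[pos]^2 / dp) + npos * sp11 - sum(dp * q11)
    S12 <- sum(G1[pos] * G2[pos] / dp) + npos * sp12 - sum(dp * q12)
    S22 <- sum(G2[pos]^2 / dp) + npos * sp22 - sum(dp * q22)
    Sp_new <- matrix(c(S11, S12, S12, S22), 2, 2) / npos
    if (constrain == "diag_psi") Sp_new[1, 2] <- Sp_new[2, 1] <- 0

    # residual M-step (diagonal): eps_i = r_i - psi_i
    E1 <- R1 - G1
    E2 <- R2 - G2
    se1 <- Se[1, 1]; se2 <- Se[2, 2]
    # conditional variance of eps: Se - Se P_ii Se (diagonal entries)
    pall11 <- i11 - xo^2 * (i11 * (Ainv[1, 1] * i11 + Ainv[1, 2] * i12) +
                              i12 * (Ainv[2, 1] * i11 + Ainv[2, 2] * i12))
    pall22 <- i22 - xo^2 * (i12 * (Ainv[1, 1] * i12 + Ainv[1, 2] * i22) +
                              i22 * (Ainv[2, 1] * i12 + Ainv[2, 2] * i22))
    T1 <- sum(E1^2) + n * se1 - se1^2 * sum(pall11)
    T2 <- sum(E2^2) + n * se2 - se2^2 * sum(pall22)
    Se_new <- diag(pmax(c(T1, T2) / n, eps_floor))

    Sp <- Sp_new
    Se <- Se_new
    # keep Sp PSD: clip correlation to [-1, 1]
    s1 <- max(Sp[1, 1], 1e-12); s2v <- max(Sp[2, 2], 1e-12)
    r12 <- Sp[1, 2] / sqrt(s1 * s2v)
    if (is.finite(r12) && abs(r12) > 1) {
      Sp[1, 2] <- Sp[2, 1] <- sign(r12) * sqrt(s1 * s2v) * (1 - 1e-10)
    }
    Sp[1, 1] <- s1; Sp[2, 2] <- s2v
    ll_old <- ll
    if (converged || it >= maxit) break
  }

  degenerate <- Sp[1, 1] < 1e-7 * v1 || Sp[2, 2] < 1e-7 * v2
  rho <- Sp[1, 2] / sqrt(Sp[1, 1] * Sp[2, 2])
  # back-rotate BLUPs
  a <- d * Sp[1, 1] + Se[1, 1]; b <- d * Sp[1, 2]
  cc <- d * Sp[2, 2] + Se[2, 2]; det <- a * cc - b^2
  i11 <- cc / det; i22 <- a / det; i12 <- -b / det
  R1 <- Y[, 1] - xo * mu[1]; R2 <- Y[, 2] - xo * mu[2]
  P1 <- i11 * R1 + i12 * R2; P2 <- i12 * R1 + i22 * R2
  G1 <- d * (Sp[1, 1] * P1 + Sp[1, 2] * P2)
  G2 <- d * (Sp[1, 2] * P1 + Sp[2, 2] * P2)
  blup <- cbind(drop(U %*% G1), drop(U %*% G2))
  rho_blup <- if (degenerate) NA_real_ else stats::cor(blup[, 1], blup[, 2])

  structure(list(Sigma_psi = Sp, Sigma_eps = Se,
                 rho_psi = unname(rho), rho_blup = rho_blup,
                 mu = mu, blup = blup, degenerate = degenerate,
                 loglik = ll_old, iterations = it, converged = converged),
            class = "bivariate_fit")
}

#' @export
print.bivariate_fit <- function(x, ...) {
  cat("Bivariate GBLUP fit\n")
  cat(sprintf("  additive covariance: [%.4g, %.4g; ., %.4g]\n",
              x$Sigma_psi[1, 1], x$Sigma_psi[1, 2], x$Sigma_psi[2, 2]))
  cat(sprintf("  rho_psi = %.4f | rho(BLUP) = %.4f%s\n",
              x$rho_psi, x$rho_blup,
              if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' Efficiency of indirect selection
#'
#' Expected response in trait j when selecting on trait i, relative to
#' direct selection on j. The default reads the ratio literally as
#' E = rho * h2_i / h2_j; `method = "falconer"` uses the conventional
#' E = rho * h_i / h_j (square-root scale).
#'
#' @param h2_i Heritability of the secondary (selection) trait.
#' @param h2_j Heritability of the target trait (> 0).
#' @param rho Additive genetic correlation between the traits.
#' @param method "literal" or "falconer".
#' @return Numeric efficiency E; E > 1 means indirect beats direct.
#' @export
indirect_efficiency <- function(h2_i, h2_j, rho,
                                method = c("literal", "falconer")) {
  method <- match.arg(method)
  if (any(h2_j <= 0)) stop("h2_j must be > 0")
  if (method == "literal") rho * h2_i / h2_j else rho * sqrt(h2_i / h2_j)
}
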
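#' Center a marker matrix
#'
#' Subtracts twice the counted-allele frequency from each column, so that
#' column means are zero: M[i, j] = code[i, j] - 2 p_j.
#'
#' @param panel A [marker_panel()] without missing codes, or a plain
#'   dosage matrix.
#' @param p Optional frequencies; default from the supplied codes.
#' @return Centered numeric matrix.
#' @export
center_markers <- function(panel, p = NULL) {
  geno <- if (inherits(panel, "marker_panel")) panel$genotypes else as.matrix(panel)
  if (anyNA(geno))
    stop("missing genotype codes; run impute_and_filter() first")
  if (is.null(p)) p <- colMeans(geno) / 2
  sweep(geno, 2, 2 * p)
}

#' Additive and additive-by-additive genomic kernels
#'
#' From the centered marker matrix M: the cross-product G = M M' is
#' trace-normalized to the additive kernel K = G * n / tr(G), and its
#' Hadamard square gives the epistatic kernel
#' Q = (G # G) * n / tr(G # G). Both have trace n by construction. The
#' Hadamard square is taken on the unnormalized G and then renormalized
#' by its own trace; a normalized K # K differs only by a scalar absorbed
#' by the normalizer.
#'
#' @param M Centered marker matrix from [center_markers()].
#' @return Object of class `kernel_set`: K, Q, alpha_K, alpha_Q.
#' @export
build_kernels <- function(M) {
  M <- as.matrix(M)
  n <- nrow(M)
  G <- tcrossprod(M)
  trG <- sum(diag(G))
  if (trG <= 0) stop("trace(MM') is zero: all markers monomorphic")
  aK <- n / trG
  GG <- G * G
  trGG <- sum(diag(GG))
  aQ <- n / trGG
  structure(list(K = G * aK, Q = GG * aQ, alpha_K = aK, alpha_Q = aQ),
            class = "kernel_set")
}

#' @export
print.kernel_set <- function(x, ...) {
  n <- nrow(x$K)
  cat("kernel_set:", n, "x", n,
      sprintf("| trace(K)=%.6g trace(Q)=%.6g\n",
              sum(diag(x$K)), sum(diag(x$Q))))
  invisible(x)
}

#' SNP-BLUP narrow-sense heritability
#'
#' Ridge-type whole-genome regression y = mu + M a + eps with
#' a ~ N(0, s2a I), REML variance components obtained on the eigenbasis
#' of M M'. Narrow-sense heritability is the ratio
#' h2 = s2a * S / (s2a * S + s2eps), where S converts the per-marker
#' effect variance into additive genetic variance, summed over the
#' markers actually fitted.
#'
#' In a Hardy-Weinberg population S = 2 sum p_j (1 - p_j). A RIL panel is
#' (nearly) fully inbred, where each biallelic marker contributes
#' (1 + F) * 2 p q = 4 p q of dosage variance, so the HW sum understates
#' the genetic variance by about half. The default scale therefore uses
#' the empirical marker-variance sum S = sum_j var(m_j) — identical to
#' 2 sum pq under HW, and self-consistent on inbred panels;
#' `scale = "hw"` gives the literal HW expression.
#'
#' Passing `subset` re-estimates s2a on that subset (the QTL-subset
#' scenario); it never reuses the all-marker estimate.
#'
#' @param y Named vector of (deregressed) genetic values.
#' @param panel A [marker_panel()] containing at least the individuals in
#'   `names(y)`.
#' @param subset Optional character vector of marker ids to fit.
#' @param scale "marker_var" (default) or "hw" for the additive-variance
#'   denominator (see Details).
#' @return Object of class `snp_blup`: mu, effects, s2a, s2eps, h2,
#'   sum2pq (HW sum), scale_sum (the S actually used), fitted, markers.
#' @export
snp_blup_h2 <- function(y, panel, subset = NULL,
                        scale = c("marker_var", "hw")) {
  scale <- match.arg(scale)
  if (is.null(names(y))) stop("y must be named by genotype id")
  idx <- match(names(y), rownames(panel$genotypes))
  if (anyNA(idx)) stop("y contains ids absent from the panel")
  geno <- panel$genotypes[idx, , drop = FALSE]
  if (!is.null(subset)) {
    if (!length(subset)) stop("empty marker subset")
    miss <- setdiff(subset, colnames(geno))
    if (length(miss))
      stop("subset markers not in panel: ", paste(miss, collapse = ", "))
    geno <- geno[, subset, drop = FALSE]
  }
  p <- colMeans(geno) / 2
  poly <- p > 0 & p < 1
  geno <- geno[, poly, drop = FALSE]
  p <- p[poly]
  if (!ncol(geno)) stop("no polymorphic markers in the requested set")
  M <- sweep(geno, 2, 2 * p)
  n <- nrow(M)

  sv <- svd(M, nu = min(n, ncol(M)), nv = 0)
  d <- c(sv$d^2, rep(0, n - length(sv$d)))
  U <- sv$u
  yt_top <- drop(crossprod(U, y))
  one_top <- drop(crossprod(U, rep(1, n)))
  # complete the rotation onto the null space of MM' implicitly:
  # squared norms of the residual projections carry eigenvalue 0
  yperp2 <- sum(y^2) - sum(yt_top^2)
  operp2 <- n - sum(one_top^2)
  yo_perp <- sum(y) - sum(yt_top * one_top)

  nd <- length(sv$d)
  obj <- function(h) {
    v <- h * d[seq_len(nd)] / mean(d) + (1 - h)
    ve <- 1 - h
    a11 <- sum(one_top^2 / v) + operp2 / ve
    b1 <- sum(yt_top * one_top / v) + yo_perp / ve
    q0 <- sum(yt_top^2 / v) + yperp2 / ve
    q <- q0 - b1^2 / a11
    s2 <- q / (n - 1)
    (n - 1) * (1 + log(s2)) + sum(log(v)) + (n - nd) * log(ve) + log(a11)
  }
  opt <- stats::optimize(obj, c(1e-9, 1 - 1e-9), tol = 1e-10)
  h <- opt$minimum
  dbar <- mean(d)
  v <- h * d[seq_len(nd)] / dbar + (1 - h)
  ve <- 1 - h
  a11 <- sum(one_top^2 / v) + operp2 / ve
  b1 <- sum(yt_top * one_top / v) + yo_perp / ve
  mu <- b1 / a11
  q <- sum(yt_top^2 / v) + yperp2 / ve - b1^2 / a11
  s2 <- q / (n - 1)
  # Var(Ma) = s2a MM'; on the scaled basis s2 * h * d/dbar => s2a = s2*h/dbar
  s2a <- s2 * h / dbar
  s2eps <- s2 * (1 - h)

  # marker effect BLUPs: a = s2a M' V^-1 (y - mu)
  rt <- (yt_top - mu * one_top) / (s2 * v)
  a_hat <- s2a * drop(crossprod(M, U %*% rt))
  names(a_hat) <- colnames(M)

  sum2pq <- 2 * sum(p * (1 - p))
  vsum <- if (scale == "hw") sum2pq else sum(colMeans(M^2))
  h2 <- s2a * vsum / (s2a * vsum + s2eps)
  structure(list(mu = mu, effects = a_hat, s2a = s2a, s2eps = s2eps,
                 h2 = unname(h2), sum2pq = sum2pq, scale_sum = vsum,
                 scale = scale,
                 fitted = mu + drop(M %*% a_hat),
                 markers = colnames(M), n = n,
                 loglik = -0.5 * (opt$objective + (n - 1) * log(2 * pi))),
            class = "snp_blup")
}

#' @export
print.snp_blup <- function(x, ...) {
  cat("SNP-BLUP fit:", length(x$markers), "markers,", x$n, "individuals\n")
  cat(sprintf("  s2a=%.4g s2eps=%.4g additive scale S=%.4g (%s)\n",
              x$s2a, x$s2eps, x$scale_sum, x$scale))
  cat(sprintf("  narrow-sense h2 = %.4f\n", x$h2))
  invisible(x)
}

#' @export
coef.snp_blup <- function(object, ...) object$effects
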
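#' Bonferroni threshold for the mixed-model scan
#'
#' Two-sided Bonferroni cutoff on the -log10(p) scale: -log10(0.025 / m).
#' @param m Number of markers tested. @param alpha Genome-wide two-sided level.
#' @return Threshold on the -log10 scale.
#' @export
mlm_threshold <- function(m, alpha = 0.05) -log10((alpha / 2) / m)

#' Model-frequency threshold for the whole-genome-regression scan
#'
#' Per-marker two-sided cutoff on -log10(1 - model frequency):
#' -log10(alpha / 2); no multiple-testing adjustment is required because
#' all markers are fitted jointly.
#' @param alpha Two-sided level. @return Threshold on the -log10 scale.
#' @export
wgr_threshold <- function(alpha = 0.05) -log10(alpha / 2)

.scan_result <- function(map, statistic, threshold, significant,
                         untested, method, extra = NULL) {
  out <- data.frame(marker = map$marker, chrom = map$chrom,
                    pos = if ("pos_bp" %in% names(map)) map$pos_bp else map$cM,
                    statistic = statistic, threshold = threshold,
                    significant = significant, untested = untested,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(list(table = out, method = method, extra = extra),
            class = "nam_scan")
}

#' @export
print.nam_scan <- function(x, ...) {
  tab <- x$table
  cat("Genome scan (", x$method, "): ", nrow(tab), " markers, ",
      sum(tab$significant), " significant at threshold ",
      round(tab$threshold[1], 3), "\n", sep = "")
  if (any(tab$significant)) {
    hits <- tab[tab$significant, c("marker", "chrom", "pos", "statistic")]
    print(utils::head(hits[order(-hits$statistic), ], 10), row.names = FALSE)
  }
  invisible(x)
}

#' Manhattan-style plot of a genome scan
#' @param x A `nam_scan`. @param ... Passed to [graphics::plot()].
#' @export
plot.nam_scan <- function(x, ...) {
  tab <- x$table
  chn <- as.integer(factor(tab$chrom))
  graphics::plot(seq_len(nrow(tab)), tab$statistic,
                 col = c("grey30", "steelblue")[1 + chn %% 2], pch = 20,
                 xlab = "marker index", ylab = "scan statistic",
                 main = paste("Genome scan:", x$method), ...)
  graphics::abline(h = tab$threshold[1], lty = 2, col = "red")
  invisible(x)
}

#' Family-nested mixed-model association scan
#'
#' Likelihood-ratio scan tailored to NAM panels. The null polygenic model
#' y = mu + psi + e (psi ~ N(0, K s2psi)) is fitted once by REML on the
#' eigenbasis of K. For each marker, the full model adds X beta where X
#' nests the marker codes within family (one column per family in which
#' the marker segregates) and beta ~ N(0, s2beta I) with a common s2beta
#' profiled by REML; the polygenic and residual components are held at
#' their null estimates so the eigendecomposition is reused across
#' markers. LRT = 2(ll_full - ll_null), with p-values from chi-square
#' with 1 df by default (`mixture = TRUE` uses the boundary-corrected
#' 0.5 chi2(0) + 0.5 chi2(1) mixture). The significance line is the
#' two-sided Bonferroni threshold -log10(0.025 / m).
#'
#' @param y Named vector of genetic values.
#' @param panel [marker_panel()] with family labels.
#' @param K Additive kernel; built from the panel when `NULL` (a ridge of
#'   1e-6 is added if needed for full rank).
#' @param mixture Use the 50:50 chi-square mixture for the boundary test.
#' @param alpha Genome-wide two-sided level for the threshold.
#' @return A `nam_scan`; statistic is -log10(p). Markers that segregate
#'   in no family are flagged `untested` with statistic 0.
#' @export
scan_mlm <- function(y, panel, K = NULL, mixture = FALSE, alpha = 0.05) {
  if (is.null(names(y))) stop("y must be named by genotype id")
  idx <- match(names(y), rownames(panel$genotypes))
  if (anyNA(idx)) stop("y contains ids absent from the panel")
  geno <- panel$genotypes[idx, , drop = FALSE]
  fam <- factor(panel$family[idx])
  if (anyNA(fam)) stop("family labels are required for the nested scan")
  n <- length(y)
  m <- ncol(geno)
  if (is.null(K)) {
    M <- center_markers(geno)
    K <- build_kernels(M)$K
  }
  ev <- eigen(K, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    K <- K + diag(1e-6, n)
    ev <- eigen(K, symmetric = TRUE)
  }
  null <- reml_eigen_2vc(y, ev)
  v0 <- null$s2g * pmax(ev$values, 0) + null$s2e
  U <- ev$vectors
  yt <- drop(crossprod(U, y))
  ot <- drop(crossprod(U, rep(1, n)))
  yD <- sum(yt^2 / v0); oD <- sum(ot^2 / v0); yoD <- sum(yt * ot / v0)
  sumlogv0 <- sum(log(v0))
  ll_null <- null$loglik

  famlev <- levels(fam)
  stat <- numeric(m); untested <- logical(m)
  thr <- mlm_threshold(m, alpha)
  for (j in seq_len(m)) {
    xj <- geno[, j]
    segfam <- famlev[vapply(famlev, function(f)
      isTRUE(stats::var(xj[fam == f]) > 1e-12), logical(1))]
    if (!length(segfam)) { stat[j] <- 0; untested[j] <- TRUE; next }
    Xf <- vapply(segfam, function(f) ifelse(fam == f, xj, 0), numeric(n))
    Xt <- crossprod(U, Xf)
    XD <- Xt / v0
    B <- crossprod(XD, Xt)          # X' D^-1 X
    bo <- drop(crossprod(Xt, ot / v0))
    by <- drop(crossprod(Xt, yt / v0))
    cB <- ncol(Xt)
    negll <- function(ls2b) {
      s2b <- exp(ls2b)
      Wm <- tryCatch(solve(diag(cB) / s2b + B), error = function(e) NULL)
      if (is.null(Wm)) return(1e10)
      ld <- determinant(diag(cB) + s2b * B, logarithm = TRUE)$modulus[1]
      yV <- yD - drop(crossprod(by, Wm %*% by))
      oV <- oD - drop(crossprod(bo, Wm %*% bo))
      yoV <- yoD - drop(crossprod(by, Wm %*% bo))
      if (oV <= 0) return(1e10)
      0.5 * ((n - 1) * log(2 * pi) + sumlogv0 + ld + log(oV) +
               (yV - yoV^2 / oV))
    }
    opt <- stats::optimize(negll, c(-25, 15), tol = 1e-8)
    ll_full <- max(-opt$objective, ll_null)
    lrt <- max(0, 2 * (ll_full - ll_null))
    p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
    if (mixture) p <- 0.5 * p
    stat[j] <- min(300, -log10(max(p, 1e-300)))
  }
  map <- panel$map
  .scan_result(map, stat, thr, stat > thr & !untested, untested,
               method = "MLM",
               extra = list(null = list(s2psi = null$s2g, s2e = null$s2e),
                            alpha = alpha, mixture = mixture))
}

#' BayesCpi whole-genome-regression scan
#'
#' Gibbs sampler in which every marker carries an inclusion indicator;
#' the exclusion probability pi is resampled each iteration from its
#' Beta full conditional (counts + 1), the common slab variance follows
#' a scaled-inverse-chi-square with nu0 = 5 and scale
#' S_beta = 0.5 var(y) / (MSx (1 - pi)) recomputed from the current pi,
#' and the residual scale is S_eps = 0.5 var(y). The association
#' statistic is -log10(1 - model frequency); the two-sided significance
#' line is -log10(0.025) = 1.6 and needs no multiplicity adjustment.
#'
#' @param y Named vector of genetic values.
#' @param panel [marker_panel()] (no missing codes).
#' @param iters,burnin MCMC chain length and discarded initial draws.
#' @param seed Optional integer seed.
#' @param nu0 Prior degrees of freedom (default 5).
#' @param alpha Two-sided per-marker level.
#' @param pi_init Initial exclusion probability.
#' @param fix_pi,fix_sigb,fix_sige Optional fixed values (diagnostics /
#'   conjugate checks); `NULL` samples them.
#' @return A `nam_scan`; extra carries model frequencies and posterior
#'   effect means.
#' @export
scan_bayescpi <- function(y, panel, iters = 20000L, burnin = 2000L,
                          seed = NULL, nu0 = 5, alpha = 0.05,
                          pi_init = 0.95, fix_pi = NULL,
                          fix_sigb = NULL, fix_sige = NULL) {
  if (iters <= burnin) stop("iters must exceed burnin")
  if (is.null(names(y))) stop("y must be named by genotype id")
  idx <- match(names(y), rownames(panel$genotypes))
  if (anyNA(idx)) stop("y contains ids absent from the panel")
  M <- center_markers(panel$genotypes[idx, , drop = FALSE])
  msx <- sum(apply(M, 2, stats::var))
  if (!is.null(seed)) set.seed(seed)
  res <- wgr_gibbs(y, M, as.integer(iters), as.integer(burnin),
                   nu0 = nu0,
                   pi_null = if (is.null(fix_pi)) pi_init else fix_pi,
                   update_pi = is.null(fix_pi),
                   per_marker_var = FALSE, msx = msx,
                   fix_sigb = if (is.null(fix_sigb)) -1 else fix_sigb,
                   fix_sige = if (is.null(fix_sige)) -1 else fix_sige)
  freq <- pmin(res$model_freq, 1 - 0.5 / res$kept)
  stat <- -log10(1 - freq)
  thr <- wgr_threshold(alpha)
  .scan_result(panel$map, stat, thr, stat > thr, rep(FALSE, ncol(M)),
               method = "WGR",
               extra = list(model_freq = res$model_freq,
                            effects = stats::setNames(res$effects, colnames(M)),
                            mu = res$mu, pi_null = res$pi_null,
                            sigma2_b = res$sigma2_b, sigma2_e = res$sigma2_e))
}

#' Random-forest regression scan with permutation threshold
#'
#' Grows a regression forest on the marker codes and ranks markers by
#' impurity (variance-reduction) importance. The significance line is
#' the global empirical threshold: the (1 - alpha) quantile of the
#' maximum importance across markers over `n_perm` phenotype
#' permutations, so no distributional assumption is made.
#'
#' @param y Named vector of genetic values.
#' @param panel [marker_panel()] (no missing codes).
#' @param n_trees Trees per forest (study default 10000).
#' @param mtry Candidate variables per split (study default 65; capped
#'   at the marker count).
#' @param n_perm Phenotype permutations for the threshold (study
#'   default 1000).
#' @param alpha Empirical significance level.
#' @param seed Optional integer seed.
#' @return A `nam_scan`; statistic is the impurity importance.
#' @export
scan_rfr <- function(y, panel, n_trees = 10000L, mtry = 65L,
                     n_perm = 1000L, alpha = 0.05, seed = NULL) {
  if (is.null(names(y))) stop("y must be named by genotype id")
  idx <- match(names(y), rownames(panel$genotypes))
  if (anyNA(idx)) stop("y contains ids absent from the panel")
  X <- panel$genotypes[idx, , drop = FALSE]
  if (anyNA(X)) stop("missing genotype codes; run impute_and_filter() first")
  m <- ncol(X)
  if (mtry > m) stop("mtry (", mtry, ") exceeds the marker count (", m, ")")
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  dat <- data.frame(y = y, X, check.names = FALSE)
  rf <- ranger::ranger(dependent.variable.name = "y", data = dat,
                       num.trees = n_trees, mtry = mtry,
                       importance = "impurity",
                       num.threads = 1,
                       seed = sample.int(.Machine$integer.max, 1))
  imp <- rf$variable.importance
  maxima <- vapply(seq_len(n_perm), function(k) {
    dat$y <- sample(y)
    rfp <- ranger::ranger(dependent.variable.name = "y", data = dat,
                          num.trees = n_trees, mtry = mtry,
                          importance = "impurity",
                          num.threads = 1,
                          seed = sample.int(.Machine$integer.max, 1))
    max(rfp$variable.importance)
  }, numeric(1))
  thr <- unname(stats::quantile(maxima, 1 - alpha, type = 7))
  .scan_result(panel$map, unname(imp), thr, unname(imp) > thr,
               rep(FALSE, m), method = "RFR",
               extra = list(perm_maxima = maxima, alpha = alpha,
                            n_trees = n_trees, mtry = mtry))
}

#' Least-squares allele-substitution effects for selected markers
#'
#' For each hit x trait, the ordinary least-squares regression of the
#' (deregressed) trait values on the marker code after removing family
#' means from both sides, so the effect reflects within-family allele
#' substitution. With the counted allele taken from the alternate
#' founders, a negative effect means the desirable allele was inherited
#' from a founder parent.
#'
#' @param y_traits Named list (or data.frame) of trait vectors, each
#'   named by genotype id.
#' @param panel [marker_panel()].
#' @param hits Character vector of marker ids.
#' @return data.frame, one row per hit, one column per trait.
#' @export
qtl_effects <- function(y_traits, panel, hits) {
  if (!length(hits)) stop("hits must be nonempty")
  miss <- setdiff(hits, colnames(panel$genotypes))
  if (length(miss)) stop("hit(s) not in panel: ", paste(miss, collapse = ", "))
  if (is.data.frame(y_traits)) y_traits <- as.list(y_traits)
  out <- data.frame(marker = hits, stringsAsFactors = FALSE)
  for (tr in names(y_traits)) {
    yv <- y_traits[[tr]]
    idx <- match(names(yv), rownames(panel$genotypes))
    if (anyNA(idx)) stop("trait '", tr, "' contains ids absent from the panel")
    fam <- panel$family[idx]
    yc <- yv - stats::ave(yv, fam)
    eff <- vapply(hits, function(h) {
      x <- panel$genotypes[idx, h]
      xc <- x - stats::ave(x, fam)
      vx <- sum(xc^2)
      if (vx < 1e-12) return(NA_real_)
      sum(xc * yc) / vx
    }, numeric(1))
    out[[tr]] <- unname(eff)
  }
  out
}

#' Consensus table across scan methods
#'
#' Per marker, the set of methods that flagged it significant (the
#' "methods detected" letters of a multi-method study) — the union of
#' the per-method significance flags.
#'
#' @param scans Named list of `nam_scan` objects over the same panel.
#' @return data.frame: marker, chrom, pos, methods (comma-joined),
#'   n_methods.
#' @export
consensus_table <- function(scans) {
  stopifnot(length(scans) >= 1)
  base <- scans[[1]]$table[, c("marker", "chrom", "pos")]
  flags <- sapply(scans, function(s) {
    s$table$significant[match(base$marker, s$table$marker)]
  })
  flags <- as.matrix(flags)
  methods <- apply(flags, 1, function(z) {
    paste(names(scans)[which(z)], collapse = ",")
  })
  data.frame(base, methods = methods, n_methods = rowSums(flags, na.rm = TRUE),
             stringsAsFactors = FALSE)
}
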
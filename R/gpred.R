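#' GBLUP predictor
#'
#' Ridge-REML genomic BLUP: the variance ratio lambda = s2e / s2u is
#' estimated by REML on the training subset of the kernel, and held-out
#' individuals are predicted through their kernel rows,
#' K[test, train] (K[train, train] + lambda I)^-1 (y - mu).
#'
#' @param y_train Named training phenotypes.
#' @param K Relationship matrix over all individuals (dimnames = ids).
#' @param lambda Optional fixed variance ratio s2e / s2u; `NULL` (the
#'   default) estimates it by REML.
#' @return Object of class `gblup_fit`; `predict()` returns values for
#'   any ids present in the kernel.
#' @export
fit_gblup <- function(y_train, K, lambda = NULL) {
  ids <- names(y_train)
  if (is.null(ids)) stop("y_train must be named by genotype id")
  tr <- match(ids, rownames(K))
  if (anyNA(tr)) stop("training ids missing from the kernel")
  Ktr <- K[tr, tr, drop = FALSE]
  if (is.null(lambda)) {
    fit <- reml_eigen_2vc(y_train, Ktr)
    lambda <- fit$s2e / max(fit$s2g, 1e-12)
    mu <- fit$beta[1]
    s2u <- fit$s2g; s2e <- fit$s2e
  } else {
    # GLS intercept at the fixed ratio
    Vi <- chol2inv(chol(Ktr + diag(lambda + 1e-12, length(tr))))
    mu <- sum(Vi %*% y_train) / sum(Vi)
    s2u <- NA_real_; s2e <- NA_real_
  }
  A <- Ktr + diag(lambda, length(tr))
  sol <- tryCatch(solve(A, y_train - mu),
                  error = function(e) solve(A + diag(1e-8, nrow(A)),
                                            y_train - mu))
  structure(list(mu = mu, s2u = s2u, s2e = s2e,
                 lambda = lambda, alpha = drop(sol), train_ids = ids, K = K),
            class = "gblup_fit")
}

#' @export
predict.gblup_fit <- function(object, ids = NULL, ...) {
  K <- object$K
  if (is.null(ids)) ids <- rownames(K)
  te <- match(ids, rownames(K))
  if (anyNA(te)) stop("unknown ids in prediction request")
  tr <- match(object$train_ids, rownames(K))
  stats::setNames(object$mu + drop(K[te, tr, drop = FALSE] %*% object$alpha),
                  ids)
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf("GBLUP fit: n=%d, s2u=%.4g, s2e=%.4g, lambda=%.4g\n",
              length(x$train_ids), x$s2u, x$s2e, x$lambda))
  invisible(x)
}

#' BayesB predictor
#'
#' Spike-and-slab whole-genome regression with a fixed null probability
#' pi = 0.95 and a per-marker slab variance, each following a
#' scaled-inverse-chi-square with nu0 = 10 prior degrees of freedom and
#' scale S_beta = 0.5 var(y) / MSx (S_eps = 0.5 var(y)), sampled by
#' Gibbs. Predictions are M beta_hat + mu_hat at the posterior means.
#'
#' @param y_train Named training phenotypes.
#' @param M Centered marker matrix over all individuals (rownames = ids).
#' @param iters,burnin Chain length / discarded draws.
#' @param pi Null-effect probability (fixed).
#' @param nu0 Prior degrees of freedom.
#' @param seed Optional integer seed.
#' @return Object of class `bayesb_fit` with posterior means; `predict()`
#'   scores any ids present in M.
#' @export
fit_bayesb <- function(y_train, M, iters = 5000L, burnin = 500L,
                       pi = 0.95, nu0 = 10, seed = NULL) {
  if (iters <= burnin) stop("iters must exceed burnin")
  ids <- names(y_train)
  if (is.null(ids)) stop("y_train must be named by genotype id")
  tr <- match(ids, rownames(M))
  if (anyNA(tr)) stop("training ids missing from the marker matrix")
  Mtr <- M[tr, , drop = FALSE]
  msx <- sum(apply(Mtr, 2, stats::var))
  if (!is.null(seed)) set.seed(seed)
  res <- wgr_gibbs(y_train, Mtr, as.integer(iters), as.integer(burnin),
                   nu0 = nu0, pi_null = pi, update_pi = FALSE,
                   per_marker_var = TRUE, msx = msx)
  structure(list(mu = res$mu,
                 effects = stats::setNames(res$effects, colnames(M)),
                 inclusion = stats::setNames(res$model_freq, colnames(M)),
                 sigma2_e = res$sigma2_e, pi = pi, nu0 = nu0,
                 train_ids = ids, M = M),
            class = "bayesb_fit")
}

#' @export
predict.bayesb_fit <- function(object, ids = NULL, ...) {
  M <- object$M
  if (is.null(ids)) ids <- rownames(M)
  te <- match(ids, rownames(M))
  if (anyNA(te)) stop("unknown ids in prediction request")
  stats::setNames(object$mu + drop(M[te, , drop = FALSE] %*% object$effects),
                  ids)
}

#' @export
print.bayesb_fit <- function(x, ...) {
  cat(sprintf("BayesB fit: n=%d, m=%d, pi(null)=%.2f, mean inclusion=%.3f\n",
              length(x$train_ids), length(x$effects), x$pi,
              mean(x$inclusion)))
  invisible(x)
}

.fit_predict <- function(model, y_train, test_ids, K, M, mcmc, seed = NULL) {
  if (model == "GBLUP") {
    f <- fit_gblup(y_train, K)
    predict(f, test_ids)
  } else {
    f <- fit_bayesb(y_train, M, iters = mcmc$iters, burnin = mcmc$burnin,
                    seed = seed)
    predict(f, test_ids)
  }
}

#' Cross-validated genomic prediction
#'
#' Evaluates predictive ability (PA: the Pearson correlation between
#' predicted and observed deregressed values) under three geometries:
#' \describe{
#'   \item{across_family}{folds drawn over the whole panel; PA pooled
#'     over the held-out set of each fold.}
#'   \item{within_family}{each family is cross-validated on its own:
#'     folds drawn within the family, the model calibrated only on the
#'     family's remaining lines, and PA computed within the family
#'     (pooling across families would inflate PA through family means;
#'     the small per-family calibration sets are part of what this
#'     scheme measures).}
#'   \item{leave_family_out}{each family in turn is predicted from all
#'     other families; PA within the left-out family.}
#' }
#' The kernel is built once on the full panel and subset per fold.
#'
#' @param y Named vector of (deregressed) genetic values.
#' @param panel [marker_panel()] (no missing codes) covering `names(y)`.
#' @param scheme One of "within_family", "across_family",
#'   "leave_family_out".
#' @param model "GBLUP" or "BayesB".
#' @param folds,reps Fold count and repetitions (random schemes only).
#' @param seed Integer seed driving all fold draws and chains.
#' @param mcmc list(iters, burnin) for BayesB.
#' @param K Optional precomputed kernel.
#' @return Object of class `nam_cv` with the per-cell PA table and
#'   summary.
#' @export
cross_validate <- function(y, panel,
                           scheme = c("across_family", "within_family",
                                      "leave_family_out"),
                           model = c("GBLUP", "BayesB"),
                           folds = 5L, reps = 25L, seed = 1L,
                           mcmc = list(iters = 5000L, burnin = 500L),
                           K = NULL) {
  scheme <- match.arg(scheme)
  model <- match.arg(model)
  if (is.null(names(y))) stop("y must be named by genotype id")
  idx <- match(names(y), rownames(panel$genotypes))
  if (anyNA(idx)) stop("y contains ids absent from the panel")
  fam <- panel$family[idx]
  if (scheme != "across_family" && anyNA(fam))
    stop("family labels are required for scheme '", scheme, "'")
  M <- center_markers(panel$genotypes[idx, , drop = FALSE])
  rownames(M) <- names(y)
  if (is.null(K)) K <- build_kernels(M)$K
  dimnames(K) <- list(names(y), names(y))
  n <- length(y)
  set.seed(seed)
  rows <- list()
  if (scheme == "leave_family_out") {
    for (f in unique(fam)) {
      te <- names(y)[fam == f]
      tr <- names(y)[fam != f]
      if (length(te) < 3 || length(tr) < 10) {
        warning("family ", f, " skipped in leave-family-out (too few lines)")
        next
      }
      pred <- .fit_predict(model, y[tr], te, K, M, mcmc)
      rows[[length(rows) + 1L]] <- data.frame(
        scheme = scheme, model = model, rep = NA_integer_,
        fold = NA_integer_, family = f,
        pa = stats::cor(pred, y[te]), n_test = length(te),
        stringsAsFactors = FALSE)
    }
  } else if (scheme == "across_family") {
    partitions <- list()
    for (r in seq_len(reps)) {
      fold_id <- sample(rep_len(seq_len(folds), n))
      partitions[[r]] <- stats::setNames(fold_id, names(y))
      for (k in seq_len(folds)) {
        te <- names(y)[fold_id == k]
        tr <- names(y)[fold_id != k]
        if (length(te) < 3) next
        pred <- .fit_predict(model, y[tr], te, K, M, mcmc)
        rows[[length(rows) + 1L]] <- data.frame(
          scheme = scheme, model = model, rep = r, fold = k,
          family = NA_character_, pa = stats::cor(pred, y[te]),
          n_test = length(te), stringsAsFactors = FALSE)
      }
    }
  } else { # within_family: calibrate on the family's own remaining lines
    for (f in unique(fam)) {
      i <- which(fam == f)
      if (length(i) < max(folds, 10L)) {
        warning("family ", f, " smaller than the fold count; skipped")
        next
      }
      for (r in seq_len(reps)) {
        fold_id <- sample(rep_len(seq_len(folds), length(i)))
        for (k in seq_len(folds)) {
          te <- names(y)[i[fold_id == k]]
          tr <- names(y)[i[fold_id != k]]
          if (length(te) < 3) next
          pred <- .fit_predict(model, y[tr], te, K, M, mcmc)
          rows[[length(rows) + 1L]] <- data.frame(
            scheme = scheme, model = model, rep = r, fold = k,
            family = f, pa = stats::cor(pred, y[te]),
            n_test = length(te), stringsAsFactors = FALSE)
        }
      }
    }
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab, scheme = scheme, model = model,
                 mean_pa = mean(tab$pa, na.rm = TRUE),
                 sd_pa = stats::sd(tab$pa, na.rm = TRUE),
                 partitions = if (scheme == "across_family") partitions
                 else NULL),
            class = "nam_cv")
}

#' @export
print.nam_cv <- function(x, ...) {
  cat(sprintf("Cross-validation [%s / %s]: %d cells, mean PA = %.3f (sd %.3f)\n",
              x$scheme, x$model, nrow(x$table), x$mean_pa, x$sd_pa))
  invisible(x)
}

#' Boxplot of cross-validation predictive abilities
#' @param x A `nam_cv` (or list of them via [c()]-style rbind upstream).
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.nam_cv <- function(x, ...) {
  graphics::boxplot(x$table$pa, main = paste(x$scheme, x$model),
                    ylab = "predictive ability", ...)
  invisible(x)
}
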
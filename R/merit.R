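#' Moving-average spatial covariate
#'
#' For every plot, the mean of the raw trait values of all other plots in
#' the same (environment, block) whose row and column distances fall
#' within the window. Plots without neighbors receive the block mean,
#' which for a single-plot block is the plot's own value.
#'
#' @param plots Plot-record data.frame with columns env, block, row, col
#'   and the trait.
#' @param trait Trait column name.
#' @param window Integer pair (rows, cols); default c(1, 1) uses the
#'   rook-plus-diagonal neighborhood.
#' @return Numeric covariate, one value per plot (in input order).
#' @export
spatial_covariate <- function(plots, trait, window = c(1, 1)) {
  if (!trait %in% names(plots)) stop("trait '", trait, "' not found in plots")
  y <- plots[[trait]]
  out <- numeric(nrow(plots))
  key <- interaction(plots$env, plots$block, drop = TRUE)
  for (g in levels(key)) {
    i <- which(key == g)
    r <- plots$row[i]; cc <- plots$col[i]; yy <- y[i]
    bm <- mean(yy, na.rm = TRUE)
    for (k in seq_along(i)) {
      nb <- abs(r - r[k]) <= window[1] & abs(cc - cc[k]) <= window[2]
      nb[k] <- FALSE
      out[i[k]] <- if (any(nb)) mean(yy[nb], na.rm = TRUE) else bm
    }
  }
  out
}

#' Per-environment precision weights
#'
#' The inverse phenotypic variance of each environment, attached to every
#' plot of that environment, to account for heteroscedasticity among
#' trials.
#'
#' @inheritParams spatial_covariate
#' @return Numeric weights, one per plot.
#' @export
env_weights <- function(plots, trait) {
  if (!trait %in% names(plots)) stop("trait '", trait, "' not found in plots")
  v <- tapply(plots[[trait]], plots$env, stats::var, na.rm = TRUE)
  if (any(is.na(v)))
    stop("each environment needs >= 2 observations to estimate its variance")
  if (any(v <= 0))
    stop("zero within-environment variance in: ",
         paste(names(v)[v <= 0], collapse = ", "))
  unname(1 / v[as.character(plots$env)])
}

#' Stage-1 genetic merit model
#'
#' Fits, per trait, the weighted mixed model
#' y = mu + beta * f(s) + Z u + W g + e, where f(s) is the moving-average
#' spatial covariate, u is the random genotype effect, g the random
#' (environment x block) effect, and the per-environment inverse
#' phenotypic variances enter as residual precision weights. Variance
#' components come from EM-REML on the mixed-model equations. Checks are
#' fitted as ordinary genotype levels but excluded from the replication
#' count r, from the reported table and from all downstream genomic
#' stages.
#'
#' Broad-sense heritability on an entry-mean basis is
#' H = s2u / (s2u + s2e / r); per-genotype reliability is
#' H_j = 1 - PEV_j / s2u, and the deregressed value is u_j / H_j.
#'
#' @inheritParams spatial_covariate
#' @param use_spatial,use_weights Toggles for the spatial covariate and
#'   the environment weights.
#' @param tol,maxit EM-REML controls.
#' @return Object of class `merit_fit`: varcomp, H, r, loglik, converged,
#'   and `table` (id, family, blup, reliability, deregressed for
#'   non-check genotypes).
#' @export
fit_merit <- function(plots, trait, window = c(1, 1),
                      use_spatial = TRUE, use_weights = TRUE,
                      tol = 1e-8, maxit = 500L) {
  if (!trait %in% names(plots)) stop("trait '", trait, "' not found in plots")
  y <- plots[[trait]]
  ok <- !is.na(y)
  plots <- plots[ok, , drop = FALSE]
  y <- y[ok]
  n <- length(y)

  X <- matrix(1, n, 1)
  if (use_spatial && all(c("row", "col") %in% names(plots))) {
    fs <- spatial_covariate(plots, trait, window)
    if (stats::sd(fs) > 1e-10) X <- cbind(X, spatial = fs)
  }
  w <- if (use_weights && length(unique(plots$env)) > 1)
    env_weights(plots, trait) else rep(1, n)

  idf <- factor(plots$id)
  Z <- stats::model.matrix(~ idf - 1)
  colnames(Z) <- levels(idf)
  Zlist <- list(genotype = Z)
  blk <- factor(paste(plots$env, plots$block, sep = ":"))
  if (nlevels(blk) > 1) {
    W <- stats::model.matrix(~ blk - 1)
    colnames(W) <- levels(blk)
    Zlist$block <- W
  }

  fit <- reml_em_mme(y, X, Zlist, weights = w, tol = tol, maxit = maxit)
  if (!fit$converged) {
    tr <- utils::tail(fit$ll_trace, 5)
    warning("EM-REML did not converge in ", maxit,
            " iterations (relative log-likelihood tolerance ", tol,
            "); last log-likelihoods: ",
            paste(sprintf("%.6f", tr), collapse = ", "))
  }
  s2u <- fit$sigma2[["genotype"]]
  s2e <- fit$sigma2[["residual"]]

  is_check <- if ("is_check" %in% names(plots)) plots$is_check else rep(FALSE, n)
  entry_counts <- table(plots$id[!is_check])
  r_bar <- if (length(entry_counts)) mean(entry_counts) else NA_real_
  H <- if (s2u > 1e-9) s2u / (s2u + s2e / r_bar) else 0

  u <- fit$u$genotype
  pev <- fit$cinv_diag$genotype * s2e
  rel <- if (s2u > 1e-9) pmax(0, pmin(1 - 1e-9, 1 - pev / s2u)) else rep(0, length(u))
  names(rel) <- names(u)
  dereg <- ifelse(rel > 1e-6, u / rel, NA_real_)

  fam_of <- plots$family[match(names(u), plots$id)]
  keep <- !(names(u) %in% unique(plots$id[is_check]))
  tab <- data.frame(id = names(u), family = fam_of,
                    blup = unname(u), reliability = unname(rel),
                    deregressed = unname(dereg),
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(tab) <- NULL

  structure(list(
    trait = trait,
    varcomp = c(s2u = unname(s2u),
                s2g = unname(if ("block" %in% names(fit$sigma2))
                  fit$sigma2[["block"]] else NA_real_),
                s2e = unname(s2e)),
    H = unname(H), r = unname(r_bar),
    beta = fit$beta,
    table = tab,
    loglik = fit$loglik,
    ll_trace = fit$ll_trace,
    iterations = fit$iterations,
    converged = fit$converged,
    degenerate = s2u <= 1e-9
  ), class = "merit_fit")
}

#' @export
print.merit_fit <- function(x, ...) {
  cat("Stage-1 genetic merit fit, trait:", x$trait, "\n")
  cat(sprintf("  variance components: s2u=%.4g s2g=%.4g s2e=%.4g\n",
              x$varcomp["s2u"], x$varcomp["s2g"], x$varcomp["s2e"]))
  cat(sprintf("  broad-sense H = %.3f (mean replication r = %.2f)\n", x$H, x$r))
  cat(sprintf("  %d entries; EM-REML %s after %d iterations\n",
              nrow(x$table),
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  if (x$degenerate)
    cat("  note: s2u ~ 0; H set to 0 and deregression undefined\n")
  invisible(x)
}

#' @export
summary.merit_fit <- function(object, ...) {
  out <- list(trait = object$trait, varcomp = object$varcomp, H = object$H,
              r = object$r,
              reliability = summary(object$table$reliability),
              loglik = object$loglik)
  class(out) <- "summary.merit_fit"
  out
}

#' @export
print.summary.merit_fit <- function(x, ...) {
  cat("merit_fit summary (", x$trait, ")\n", sep = "")
  print(x$varcomp)
  cat("H =", round(x$H, 4), "; r =", round(x$r, 3), "\n")
  cat("reliability distribution:\n")
  print(x$reliability)
  invisible(x)
}

#' @export
coef.merit_fit <- function(object, ...) {
  stats::setNames(object$table$blup, object$table$id)
}

#' Deregressed genetic values from a merit fit
#'
#' @param fit A `merit_fit`.
#' @param min_reliability Entries below this reliability are dropped.
#' @return Named numeric vector of deregressed BLUPs.
#' @export
deregressed <- function(fit, min_reliability = 0) {
  stopifnot(inherits(fit, "merit_fit"))
  tab <- fit$table
  keep <- !is.na(tab$deregressed) & tab$reliability >= min_reliability
  stats::setNames(tab$deregressed[keep], tab$id[keep])
}
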
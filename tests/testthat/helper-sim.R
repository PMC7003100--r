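# Shared fixture builders: everything is generated in code, seeded.

small_cfg <- function(seed = 1L, ...) {
  args <- list(n_families = 3L, n_ril_per_family = 40L, n_chrom = 3L,
               markers_per_chrom = 20L, n_environments = 2L,
               h2_additive_target = 0.25, h2_epistatic_target = 0.05,
               n_qtl_additive = 15L, n_qtl_epistatic_pairs = 5L,
               gxe_sd = 0.1, spatial_gradient_sd = 0.15,
               check_ratio = 7L, missing_rate = 0.02, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# Genotype-level trait: one plot per RIL, no checks/spatial/GxE, so plot
# means equal the single plot value and heritability targets apply directly.
sim_genetic_trait <- function(seed, n_families, n_ril, n_chrom = 10L,
                              markers_per_chrom = 50L, h2a = 0.25,
                              h2e = 0, n_qtl = 40L, n_pairs = 0L,
                              maf_range = c(0.2, 0.5)) {
  cfg <- sim_config(n_families = n_families, n_ril_per_family = n_ril,
                    n_chrom = n_chrom, markers_per_chrom = markers_per_chrom,
                    n_environments = 1L, h2_additive_target = h2a,
                    h2_epistatic_target = h2e, n_qtl_additive = n_qtl,
                    n_qtl_epistatic_pairs = n_pairs,
                    founder_maf_range = maf_range,
                    gxe_sd = 0, spatial_gradient_sd = 0,
                    check_ratio = 0L, missing_rate = 0, seed = seed)
  map <- make_genetic_map(cfg)
  founders <- simulate_founders(cfg, map)
  rils <- derive_rils(founders, map, cfg)
  ph <- simulate_phenotypes(rils, cfg, founders = founders)
  y <- tapply(ph$plots$y, ph$plots$id, mean)[rownames(rils$genotypes)]
  list(panel = rils, founders = founders,
       y = stats::setNames(as.numeric(y), rownames(rils$genotypes)),
       truth = ph$truth, cfg = cfg)
}

# Direct evaluator of the restricted log-likelihood (-2ll, profiled total
# variance) used as the independent grid-search oracle. V is expressed as
# a convex combination of the supplied covariance structures.
m2ll_profiled <- function(y, parts, weights) {
  n <- length(y)
  V <- Reduce(`+`, Map(`*`, parts, weights))
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) return(Inf)
  Vi <- chol2inv(cV)
  X <- matrix(1, n, 1)
  A <- drop(crossprod(X, Vi %*% X))
  b <- drop(crossprod(X, Vi %*% y))
  qf <- drop(crossprod(y, Vi %*% y)) - b^2 / A
  s2 <- qf / (n - 1)
  (n - 1) * (1 + log(s2)) + 2 * sum(log(diag(cV))) + log(A)
}
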
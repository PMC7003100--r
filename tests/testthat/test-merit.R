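make_block <- function(vals, nrow, ncol, env = "E1", block = "B1") {
  data.frame(id = paste0("g", seq_along(vals)), family = "F01",
             env = env, year = "Y1", loc = "L1", block = block,
             row = rep(seq_len(nrow), each = ncol)[seq_along(vals)],
             col = rep(seq_len(ncol), nrow)[seq_along(vals)],
             is_check = FALSE, y = vals)
}

test_that("moving-average covariate matches hand enumeration", {
  # 3x3 block, values 1..9, window (1,1): center neighbor mean = 4.5
  pl <- make_block(1:9, 3, 3)
  cov <- spatial_covariate(pl, "y", window = c(1, 1))
  center <- which(pl$row == 2 & pl$col == 2)
  expect_equal(cov[center], mean(c(1, 2, 3, 4, 6, 7, 8, 9)))
  # corner plot: neighbors 2, 4, 5
  corner <- which(pl$row == 1 & pl$col == 1)
  expect_equal(cov[corner], mean(c(2, 4, 5)))

  # spatially constant trait -> covariate constant at that value
  plc <- make_block(rep(7, 9), 3, 3)
  expect_true(all(spatial_covariate(plc, "y") == 7))

  # single-plot block falls back to the block mean (itself)
  pl1 <- make_block(3.5, 1, 1)
  expect_equal(spatial_covariate(pl1, "y"), 3.5)

  expect_error(spatial_covariate(pl, "nope"), "nope")
})

test_that("environment weights are inverse phenotypic variances", {
  pl <- rbind(make_block(c(0, 2), 1, 2, env = "E1"),
              make_block(c(10, 14), 1, 2, env = "E2"))
  w <- env_weights(pl, "y")
  expect_equal(w[pl$env == "E1"][1], 1 / var(c(0, 2)))
  expect_equal(w[pl$env == "E2"][1], 1 / var(c(10, 14)))
  expect_equal(w[pl$env == "E1"][1] / w[pl$env == "E2"][1], 4)

  # equal-variance environments differing only in mean get equal weights
  pl2 <- rbind(make_block(c(0, 2, 4), 1, 3, env = "E1"),
               make_block(c(100, 102, 104), 1, 3, env = "E2"))
  w2 <- env_weights(pl2, "y")
  expect_equal(unname(w2[1]), unname(w2[4]))

  pl3 <- rbind(make_block(c(1, 1), 1, 2, env = "E1"),
               make_block(c(0, 2), 1, 2, env = "E2"))
  expect_error(env_weights(pl3, "y"), "zero within-environment variance")
})

test_that("merit fit recovers EM-REML components matching a grid oracle", {
  # 30 plots, two variance components (genotype + residual)
  set.seed(404)
  n <- 30L; q <- 12L
  id <- sample(rep(paste0("g", 1:q), length.out = n))
  u <- rnorm(q, 0, sqrt(0.6))
  pl <- data.frame(id = id, family = "F01", env = "E1", year = "Y1",
                   loc = "L1", block = "B1",
                   row = rep(1:5, each = 6), col = rep(1:6, 5),
                   is_check = FALSE,
                   y = 2 + u[match(id, paste0("g", 1:q))] +
                     rnorm(n, 0, sqrt(0.4)))
  fit <- fit_merit(pl, "y", use_spatial = FALSE, use_weights = FALSE,
                   tol = 1e-10, maxit = 2000)
  h_em <- fit$varcomp[["s2u"]] / (fit$varcomp[["s2u"]] + fit$varcomp[["s2e"]])

  Z <- model.matrix(~ factor(pl$id) - 1)
  hs <- seq(0.001, 0.999, by = 0.001)
  vals <- vapply(hs, function(h)
    m2ll_profiled(pl$y, list(tcrossprod(Z), diag(n)), c(h, 1 - h)),
    numeric(1))
  h_grid <- hs[which.min(vals)]
  expect_lt(abs(h_em - h_grid), 1.5e-3)
})

test_that("unit weights reproduce the unweighted fit", {
  sim <- simulate_nam(small_cfg(seed = 41L, n_environments = 2L))
  f_w <- fit_merit(sim$plots, "y", use_weights = TRUE)
  # same model with all weights forced equal via a single-env subset
  one_env <- sim$plots[sim$plots$env == "E1", , drop = FALSE]
  f_u1 <- fit_merit(one_env, "y", use_weights = TRUE)
  f_u2 <- fit_merit(one_env, "y", use_weights = FALSE)
  expect_equal(f_u1$varcomp, f_u2$varcomp, tolerance = 1e-10)
  expect_equal(coef(f_u1), coef(f_u2), tolerance = 1e-10)
  expect_s3_class(f_w, "merit_fit")
})

test_that("heritability is scale invariant and BLUPs are shrunk", {
  sim <- simulate_nam(small_cfg(seed = 43L))
  f1 <- fit_merit(sim$plots, "y")
  pl2 <- sim$plots; pl2$y <- pl2$y * 7.3
  f2 <- fit_merit(pl2, "y")
  expect_equal(f1$H, f2$H, tolerance = 1e-5)
  expect_true(f1$H >= 0 && f1$H <= 1)

  tab <- f1$table
  ok <- tab$reliability > 1e-6
  # deregression undoes shrinkage: |blup| <= |deregressed|, equality at H_j=1
  expect_true(all(abs(tab$blup[ok]) <= abs(tab$deregressed[ok]) + 1e-12))
  expect_equal(tab$deregressed[ok], tab$blup[ok] / tab$reliability[ok])
  expect_lt(var(tab$blup[ok]), var(tab$deregressed[ok]))
  # checks excluded from the reported table
  expect_false(any(grepl("^CHK", tab$id)))
})

test_that("entry-mean heritability recovers the simulated truth", {
  # 6 environments, plot-level genetic fraction 0.085 -> true H ~ 0.358
  Hs <- vapply(1:10, function(s) {
    cfg <- sim_config(n_families = 8L, n_ril_per_family = 35L, n_chrom = 5L,
                      markers_per_chrom = 30L, n_environments = 6L,
                      h2_additive_target = 0.07, h2_epistatic_target = 0.015,
                      n_qtl_additive = 40L, n_qtl_epistatic_pairs = 10L,
                      gxe_sd = 0.1, spatial_gradient_sd = 0.15,
                      check_ratio = 7L, missing_rate = 0, seed = 97L * s)
    sim <- simulate_nam(cfg)
    suppressWarnings(fit_merit(sim$plots, "y"))$H
  }, numeric(1))
  G <- 0.085
  H_true <- 6 * G / (5 * G + 1)
  expect_lt(abs(mean(Hs) - H_true), 0.07)
})
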
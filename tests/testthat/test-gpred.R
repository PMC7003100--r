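test_that("GBLUP limits: interpolation at lambda ~ 0, mean at lambda -> Inf", {
  # more markers than individuals so K is full rank and the ridgeless
  # limit genuinely interpolates
  s <- sim_genetic_trait(121L, 3L, 40L, n_chrom = 5L, markers_per_chrom = 50L)
  K <- build_kernels(center_markers(s$panel))$K
  dimnames(K) <- list(names(s$y), names(s$y))
  f0 <- fit_gblup(s$y, K, lambda = 1e-10)
  expect_equal(unname(predict(f0, names(s$y))), unname(s$y),
               tolerance = 1e-5)
  finf <- fit_gblup(s$y, K, lambda = 1e10)
  pr <- predict(finf, names(s$y))
  expect_lt(max(abs(pr - mean(s$y))), 1e-4 * sd(s$y))
})

test_that("GBLUP equals SNP-BLUP ridge predictions at the matching ratio", {
  s <- sim_genetic_trait(123L, 4L, 50L, n_chrom = 4L, markers_per_chrom = 25L)
  snp <- snp_blup_h2(s$y, s$panel)
  M <- center_markers(subset_panel(s$panel, markers = snp$markers))
  G <- tcrossprod(M)
  dimnames(G) <- list(names(s$y), names(s$y))
  gb <- fit_gblup(s$y, G, lambda = snp$s2eps / snp$s2a)
  pred_snp <- snp$mu + drop(M %*% snp$effects)
  expect_equal(unname(predict(gb, names(s$y))), unname(pred_snp),
               tolerance = 1e-6)
})

test_that("BayesB respects its spike prior on null data and is deterministic", {
  s <- sim_genetic_trait(125L, 4L, 50L, n_chrom = 4L, markers_per_chrom = 25L)
  M <- center_markers(s$panel)
  rownames(M) <- names(s$y)
  set.seed(126)
  ynull <- stats::setNames(rnorm(length(s$y)), names(s$y))
  fb <- fit_bayesb(ynull, M, iters = 3000, burnin = 500, seed = 8L)
  # prior dominance: no marker is systematically selected
  expect_lt(mean(fb$inclusion), 0.05 + 3 * sqrt(0.05 * 0.95 / 2500))
  expect_gt(mean(fb$inclusion), 0.005)
  expect_lt(max(fb$inclusion), 0.5)

  fb2 <- fit_bayesb(ynull, M, iters = 800, burnin = 100, seed = 8L)
  fb3 <- fit_bayesb(ynull, M, iters = 800, burnin = 100, seed = 8L)
  expect_identical(fb2$effects, fb3$effects)
  expect_identical(predict(fb2), predict(fb3))
})

test_that("BayesB locks onto a strong single QTL", {
  s <- sim_genetic_trait(127L, 10L, 100L, n_chrom = 5L,
                         markers_per_chrom = 20L, h2a = 0.4, n_qtl = 1L)
  M <- center_markers(s$panel)
  rownames(M) <- names(s$y)
  fb <- fit_bayesb(s$y, M, iters = 3000, burnin = 500, seed = 12L)
  qtl <- s$truth$qtl_positions[1]
  # the QTL column (or a tightly linked neighbor) carries high inclusion
  window <- max(1, qtl - 2):min(ncol(M), qtl + 2)
  expect_gt(max(fb$inclusion[window]), 0.9)
})

test_that("cross-validation folds partition the panel exactly", {
  s <- sim_genetic_trait(129L, 3L, 40L, n_chrom = 3L, markers_per_chrom = 15L)
  cv <- cross_validate(s$y, s$panel, scheme = "across_family",
                       model = "GBLUP", folds = 5, reps = 2, seed = 3L)
  for (p in cv$partitions) {
    expect_setequal(names(p), names(s$y))          # full cover
    expect_true(all(table(p) >= 1))                # every fold non-empty
    expect_equal(sum(table(p)), length(s$y))       # no overlap
  }
  # each (rep, fold) cell appears once with the pooled test size
  expect_equal(nrow(cv$table), 10L)
  expect_equal(sum(cv$table$n_test), 2L * length(s$y))
})

test_that("perfect and null predictors bound the predictive ability", {
  # noiseless fully-genetic trait + near-interpolating model: PA = 1
  s <- sim_genetic_trait(131L, 3L, 40L, n_chrom = 4L, markers_per_chrom = 20L)
  g <- s$truth$true_genetic_values[names(s$y)]
  K <- build_kernels(center_markers(s$panel))$K
  dimnames(K) <- list(names(s$y), names(s$y))
  f <- fit_gblup(g, K, lambda = 1e-10)
  expect_equal(stats::cor(predict(f, names(g)), g), 1, tolerance = 1e-6)

  # pure-noise trait: mean PA within 3 SE of zero
  set.seed(132)
  ynull <- stats::setNames(rnorm(length(s$y)), names(s$y))
  cv <- cross_validate(ynull, s$panel, scheme = "across_family",
                       model = "GBLUP", folds = 5, reps = 5, seed = 5L)
  se <- cv$sd_pa / sqrt(nrow(cv$table))
  expect_lt(abs(cv$mean_pa), 3 * se + 0.05)
})

test_that("within-family and leave-family-out schemes respect family walls", {
  s <- sim_genetic_trait(133L, 4L, 40L, n_chrom = 3L, markers_per_chrom = 15L)
  lfo <- cross_validate(s$y, s$panel, scheme = "leave_family_out",
                        model = "GBLUP", seed = 7L)
  expect_setequal(lfo$table$family, unique(s$panel$family))
  expect_equal(nrow(lfo$table), 4L)

  wf <- cross_validate(s$y, s$panel, scheme = "within_family",
                       model = "GBLUP", folds = 5, reps = 2, seed = 7L)
  expect_setequal(unique(wf$table$family), unique(s$panel$family))
  # 4 families x 2 reps x 5 folds
  expect_equal(nrow(wf$table), 40L)
  expect_true(all(wf$table$n_test < 40))
})
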
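test_that("scan thresholds follow their closed forms", {
  expect_equal(mlm_threshold(100), -log10(0.025 / 100))
  expect_equal(wgr_threshold(0.05), -log10(0.025))
  s <- sim_genetic_trait(101L, 3L, 30L, n_chrom = 3L, markers_per_chrom = 15L)
  sc <- scan_mlm(s$y, s$panel)
  expect_equal(sc$table$threshold[1],
               mlm_threshold(ncol(s$panel$genotypes)))
})

test_that("MLM scan handles non-segregating markers and is scale invariant", {
  s <- sim_genetic_trait(103L, 3L, 40L, n_chrom = 3L, markers_per_chrom = 15L)
  pan <- s$panel
  # plant a marker fixed in every family
  pan$genotypes[, 5] <- 2
  sc1 <- scan_mlm(s$y, pan)
  expect_equal(sc1$table$statistic[5], 0)
  expect_true(sc1$table$untested[5])
  expect_false(sc1$table$significant[5])

  sc2 <- scan_mlm(s$y * 3.7 + 11, pan)
  expect_equal(sc1$table$statistic, sc2$table$statistic, tolerance = 1e-5)
})

test_that("BayesCpi matches the conjugate closed form with fixed variances", {
  set.seed(105)
  n <- 200
  x <- rnorm(n)
  y <- 0.7 * x + rnorm(n)
  X <- matrix(x - mean(x), ncol = 1)
  sigb <- 10; sige <- 1
  res <- namqg:::wgr_gibbs(y - mean(y), X, 20000L, 2000L, nu0 = 1e-6,
                           pi_null = 0, update_pi = FALSE,
                           per_marker_var = FALSE, msx = var(x),
                           fix_sigb = sigb, fix_sige = sige)
  cc <- sum(X^2) + sige / sigb
  closed <- sum(X * (y - mean(y))) / cc
  mcse <- sqrt(sige / cc) / sqrt(1800)  # ~10x autocorrelation inflation
  expect_lt(abs(res$effects - closed), 3 * mcse)
})

test_that("BayesCpi statistics are valid and bit-reproducible under seed", {
  s <- sim_genetic_trait(107L, 3L, 40L, n_chrom = 3L, markers_per_chrom = 15L)
  a <- scan_bayescpi(s$y, s$panel, iters = 1200, burnin = 200, seed = 9L)
  b <- scan_bayescpi(s$y, s$panel, iters = 1200, burnin = 200, seed = 9L)
  expect_identical(a$table$statistic, b$table$statistic)
  expect_true(all(a$extra$model_freq >= 0 & a$extra$model_freq <= 1))
  expect_true(all(is.finite(a$table$statistic)))
  expect_equal(a$table$threshold[1], wgr_threshold(0.05))
  expect_error(scan_bayescpi(s$y, s$panel, iters = 100, burnin = 100),
               "burnin")
})

test_that("random-forest scan finds a noiseless signal and bounds alpha", {
  s <- sim_genetic_trait(109L, 3L, 40L, n_chrom = 4L, markers_per_chrom = 15L)
  pan <- s$panel
  y <- stats::setNames(as.numeric(pan$genotypes[, 30]),
                       rownames(pan$genotypes))
  sc <- scan_rfr(y, pan, n_trees = 300, mtry = 15, n_perm = 5, seed = 10L)
  expect_equal(which.max(sc$table$statistic), 30L)

  # alpha = 1 -> threshold at the minimum permuted maximum
  sc2 <- scan_rfr(y, pan, n_trees = 100, mtry = 10, n_perm = 8,
                  alpha = 1, seed = 11L)
  expect_equal(sc2$table$threshold[1], min(sc2$extra$perm_maxima))

  expect_error(scan_rfr(y, pan, n_trees = 100, mtry = 1e5, n_perm = 2),
               "mtry")
})

test_that("scaled-down forests keep a strong QTL at rank one", {
  # 500-tree scans must preserve the top-importance position of a QTL
  # explaining ~30% of the variance in >= 9/10 seeds
  hits <- vapply(1:10, function(s) {
    sm <- sim_genetic_trait(300L + s, 3L, 70L, n_chrom = 3L,
                            markers_per_chrom = 20L, h2a = 0.30, n_qtl = 1L)
    sc <- scan_rfr(sm$y, sm$panel, n_trees = 500, mtry = 10, n_perm = 2,
                   seed = 400L + s)
    which.max(sc$table$statistic) == sm$truth$qtl_positions[1]
  }, logical(1))
  expect_gte(sum(hits), 9L)
})

test_that("allele-substitution effects behave under coding and truth", {
  # planted QTL with effect +0.5 per allele copy at n = 2000
  s <- sim_genetic_trait(111L, 20L, 100L, n_chrom = 5L,
                         markers_per_chrom = 20L, h2a = 0, n_qtl = 1L)
  qtl <- colnames(s$panel$genotypes)[50]
  set.seed(112)
  y <- 0.5 * s$panel$genotypes[, qtl] + rnorm(2000, 0, 1)
  names(y) <- rownames(s$panel$genotypes)
  eff <- qtl_effects(list(trait = y), s$panel, qtl)
  expect_lt(abs(eff$trait - 0.5), 0.1)

  # flipping the marker coding flips the sign, not the magnitude
  pan2 <- s$panel
  pan2$genotypes[, qtl] <- 2 - pan2$genotypes[, qtl]
  eff2 <- qtl_effects(list(trait = y), pan2, qtl)
  expect_equal(eff2$trait, -eff$trait, tolerance = 1e-10)

  # marker orthogonal to the trait: effect near zero
  far <- colnames(s$panel$genotypes)[1]
  eff0 <- qtl_effects(list(trait = y), s$panel, far)
  expect_lt(abs(eff0$trait), 0.1)

  expect_error(qtl_effects(list(trait = y), s$panel, character(0)),
               "nonempty")
  expect_error(qtl_effects(list(trait = y), s$panel, "ghost"), "ghost")
})

test_that("consensus table is the exact union of per-method flags", {
  s <- sim_genetic_trait(113L, 3L, 30L, n_chrom = 3L, markers_per_chrom = 10L)
  sc1 <- scan_mlm(s$y, s$panel)
  sc2 <- scan_bayescpi(s$y, s$panel, iters = 600, burnin = 100, seed = 1L)
  # force known flags to make the bookkeeping check exact
  sc1$table$significant <- rep(c(TRUE, FALSE), length.out = 30)
  sc2$table$significant <- rep(c(TRUE, TRUE, FALSE), length.out = 30)
  cons <- consensus_table(list(M = sc1, W = sc2))
  expect_equal(cons$n_methods,
               sc1$table$significant + sc2$table$significant)
  both <- sc1$table$significant & sc2$table$significant
  expect_true(all(cons$methods[both] == "M,W"))
  none <- !sc1$table$significant & !sc2$table$significant
  expect_true(all(cons$methods[none] == ""))
})
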
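test_that("founder simulation gives inbred codes with the requested structure", {
  cfg <- small_cfg(n_families = 2L, n_chrom = 1L, markers_per_chrom = 5L)
  fo <- simulate_founders(cfg)
  expect_equal(dim(fo$genotypes), c(3L, 5L))
  expect_true(all(fo$genotypes %in% c(0, 2)))
  # common parent carries none of the counted alleles
  expect_true(all(fo$genotypes[1, ] == 0))

  fo2 <- simulate_founders(cfg)
  expect_identical(fo$genotypes, fo2$genotypes)
})

test_that("founder allele frequencies follow the configured range", {
  # p fixed at 0.5: mean counted-allele frequency among the alternate
  # founders should sit within 3 binomial SD of 0.5
  cfg <- small_cfg(n_families = 30L, n_chrom = 2L, markers_per_chrom = 25L,
                   founder_maf_range = c(0.5, 0.5), seed = 7L)
  fo <- simulate_founders(cfg)
  alt <- fo$genotypes[-1, ] / 2
  n_draws <- length(alt)
  se <- sqrt(0.25 / n_draws)
  expect_lt(abs(mean(alt) - 0.5), 3 * se)
  expect_true(all(colSums(alt) > 0))  # every locus polymorphic at p=0.5
})

test_that("invalid configurations name the offending field", {
  expect_error(small_cfg(n_ril_per_family = 1L), "n_ril_per_family")
  expect_error(small_cfg(founder_maf_range = c(0, 0.6)), "founder_maf_range")
  expect_error(small_cfg(h2_additive_target = 0.7, h2_epistatic_target = 0.4),
               "h2_additive_target")
})

test_that("meiosis respects the genetic map", {
  cfg <- small_cfg(n_families = 1L, n_ril_per_family = 300L, n_chrom = 2L,
                   markers_per_chrom = 2L, chrom_length_cM = 50, seed = 3L)
  # map with two completely linked loci on chr 1 (d = 0)
  map <- data.frame(marker = c("Gm01_1", "Gm01_2", "Gm02_1", "Gm02_2"),
                    chrom = c(1, 1, 2, 2), cM = c(10, 10, 0, 40))
  geno <- rbind(CP = c(0, 0, 0, 0), FP = c(2, 2, 2, 2))
  colnames(geno) <- map$marker
  founders <- marker_panel(geno, map, family = c(NA, NA))
  rils <- derive_rils(founders, map, cfg)
  # zero distance: alleles at the two chr-1 loci never separate
  expect_true(all(rils$genotypes[, 1] == rils$genotypes[, 2]))

  # unlinked loci (different chromosomes): gametes from an F1 recombine
  # freely; recombinant-class frequency ~ 0.5 over >= 1000 gametes
  set.seed(11)
  rfrac <- namqg:::.recomb_fractions(map)
  H1 <- matrix(0L, 1000, 4)  # common-parent haplotype
  H2 <- matrix(1L, 1000, 4)  # founder haplotype
  g <- namqg:::.meiosis(H1, H2, rfrac)
  recomb <- g[, 2] != g[, 3]   # different grandparental origin at chr1 vs chr2
  se <- sqrt(0.25 / 1000)
  expect_lt(abs(mean(recomb) - 0.5), 3 * se)
})

test_that("selfing halves heterozygosity each generation", {
  cfg <- small_cfg(n_families = 2L, n_ril_per_family = 400L, n_chrom = 2L,
                   markers_per_chrom = 10L, selfing_generations = 5L,
                   founder_maf_range = c(0.5, 0.5), seed = 5L)
  map <- make_genetic_map(cfg)
  fo <- simulate_founders(cfg, map)
  rils <- derive_rils(fo, map, cfg)
  seg <- which(fo$genotypes[1, ] != fo$genotypes[2, ])
  het <- mean(rils$genotypes[seq_len(400), seg] == 1)
  exp_het <- 0.5^5                     # F1 fully het at segregating loci
  n_cells <- 400 * length(seg)
  se <- sqrt(exp_het * (1 - exp_het) / n_cells)
  expect_lt(abs(het - exp_het), 3 * se)
})

test_that("RIL genomes are mosaics of the two family founders", {
  cfg <- small_cfg(seed = 9L)
  map <- make_genetic_map(cfg)
  fo <- simulate_founders(cfg, map)
  rils <- derive_rils(fo, map, cfg)
  expect_true(all(rils$genotypes %in% c(0, 1, 2)))
  for (f in seq_len(cfg$n_families)) {
    rows <- which(rils$family == sprintf("F%02d", f))
    same <- which(fo$genotypes[1, ] == fo$genotypes[f + 1, ])
    # where the parents agree, every RIL must carry that very genotype
    expect_true(all(rils$genotypes[rows, same] ==
                      matrix(fo$genotypes[1, same], length(rows),
                             length(same), byrow = TRUE)))
  }
})

test_that("map/panel dimension mismatch is an explicit error", {
  cfg <- small_cfg()
  map <- make_genetic_map(cfg)
  fo <- simulate_founders(cfg, map)
  expect_error(derive_rils(fo, map[-1, ], cfg), "dimension")
})

test_that("phenotype generator hits its variance budget and limits", {
  # pure-noise limit: zero heritability targets
  s0 <- sim_genetic_trait(21L, 4L, 60L, h2a = 0, h2e = 0, n_qtl = 10L)
  expect_true(all(s0$truth$true_genetic_values == 0))

  # noiseless limit: plot values equal mu + g exactly
  cfg <- small_cfg(n_environments = 1L, gxe_sd = 0, spatial_gradient_sd = 0,
                   check_ratio = 0L, missing_rate = 0, seed = 13L)
  map <- make_genetic_map(cfg)
  fo <- simulate_founders(cfg, map)
  rils <- derive_rils(fo, map, cfg)
  ph <- simulate_phenotypes(rils, cfg, mu = 5, residual_sd = 0)
  g <- ph$truth$true_genetic_values[ph$plots$id]
  expect_equal(ph$plots$y, unname(5 + g), tolerance = 1e-12)

  # over-committed variance budget is a configuration error
  cfg_bad <- small_cfg(h2_additive_target = 0.6, h2_epistatic_target = 0.3,
                       gxe_sd = 0.4)
  map2 <- make_genetic_map(cfg_bad)
  fo2 <- simulate_founders(cfg_bad, map2)
  rl2 <- derive_rils(fo2, map2, cfg_bad)
  expect_error(simulate_phenotypes(rl2, cfg_bad, founders = fo2),
               "configuration error")
})

test_that("simulation truth is internally consistent", {
  sim <- simulate_nam(small_cfg(seed = 17L))
  tr <- sim$truth
  expect_true(all(diff(tr$qtl_positions) > 0))
  expect_true(all(tr$qtl_positions >= 1 &
                    tr$qtl_positions <= ncol(sim$panel$genotypes)))
  expect_length(tr$true_genetic_values, nrow(sim$panel$genotypes))
  expect_setequal(names(tr$true_genetic_values),
                  rownames(sim$panel$genotypes))
})

test_that("a seeded study is bit-reproducible end to end", {
  a <- simulate_nam(small_cfg(seed = 23L))
  b <- simulate_nam(small_cfg(seed = 23L))
  expect_identical(a$panel$genotypes, b$panel$genotypes)
  expect_identical(a$plots, b$plots)
  expect_identical(a$truth$qtl_effects, b$truth$qtl_effects)
})

test_that("realized variance proportions match the configured targets", {
  s <- sim_genetic_trait(31L, 20L, 100L, n_chrom = 10L,
                         markers_per_chrom = 30L,
                         h2a = 0.3, h2e = 0.1, n_qtl = 100L, n_pairs = 50L)
  gA <- s$truth$true_h2_additive
  gE <- s$truth$true_h2_epistatic
  expect_lt(abs(gA - 0.3), 0.07)
  expect_lt(abs(gE - 0.1), 0.07)
  # and the phenotype variance is near its unit budget at n = 2000
  expect_lt(abs(var(s$y) - 1), 0.15)
})
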
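test_that("panel writing and reading round-trips exactly", {
  sim <- simulate_nam(small_cfg(seed = 2L))
  d <- withr::local_tempdir()
  gp <- file.path(d, "geno.tsv"); mp <- file.path(d, "map.tsv")
  fp <- file.path(d, "fam.tsv")
  write_panel(sim$panel, gp, mp, fp)
  back <- read_panel(gp, mp, fp)
  expect_identical(unname(back$genotypes), unname(sim$panel$genotypes))
  expect_identical(rownames(back$genotypes), rownames(sim$panel$genotypes))
  expect_identical(back$family, sim$panel$family)
  expect_equal(back$map$cM, sim$panel$map$cM)
})

test_that("minimal VCF genotypes map to dosage codes", {
  d <- withr::local_tempdir()
  vcf <- file.path(d, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\tmkB\tG\tC\t.\tPASS\t.\tGT:DP\t./.:3\t1|0:5\t0|0:9"
  ), vcf)
  p <- read_vcf_panel(vcf)
  expect_equal(dim(p$genotypes), c(3L, 2L))
  expect_equal(unname(p$genotypes[, 1]), c(0, 1, 2))
  expect_equal(unname(p$genotypes[, 2]), c(NA, 1, 0))
  expect_equal(colnames(p$genotypes), c("Gm1_100", "mkB"))
})

test_that("validation rejects malformed panels by name", {
  map <- data.frame(marker = c("m1", "m1"), chrom = 1, cM = c(0, 1))
  g <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("a", "b"), map$marker))
  expect_error(marker_panel(g, map), "m1")

  map2 <- data.frame(marker = c("m1", "m2"), chrom = 1, cM = c(2, 1))
  g2 <- matrix(0, 2, 2, dimnames = list(c("a", "b"), map2$marker))
  expect_error(marker_panel(g2, map2), "sorted")

  map3 <- data.frame(marker = "m1", chrom = 1, cM = 0)
  expect_error(marker_panel(matrix(3, 2, 1,
                                   dimnames = list(c("a", "b"), "m1")),
                            map3), "codes")
})

test_that("within-family modal imputation matches a hand-built oracle", {
  map <- data.frame(marker = paste0("m", 1:3), chrom = 1, cM = 0:2)
  # family A modes: m1 -> 2, m2 -> 0 ; family B modes: m1 -> 0, m2 -> 2
  # m3 is entirely unobserved in family B -> global mode (0)
  g <- rbind(
    A1 = c(2, 0, 0), A2 = c(2, 0, 0), A3 = c(NA, NA, 2),
    B1 = c(0, 2, NA), B2 = c(0, 2, NA), B3 = c(NA, NA, NA))
  colnames(g) <- map$marker
  pan <- marker_panel(g, map, family = c("A", "A", "A", "B", "B", "B"))
  out <- impute_and_filter(pan, maf_min = 0)
  expected <- rbind(
    A1 = c(2, 0, 0), A2 = c(2, 0, 0), A3 = c(2, 0, 2),
    B1 = c(0, 2, 0), B2 = c(0, 2, 0), B3 = c(0, 2, 0))
  colnames(expected) <- map$marker
  expect_identical(out$genotypes, expected)
  expect_equal(attr(out, "qc")$n_imputed, 7L)
  # observed calls untouched
  obs <- !is.na(g)
  expect_identical(out$genotypes[obs], g[obs])
})

test_that("MAF filter removes below-threshold markers and is idempotent", {
  map <- data.frame(marker = paste0("m", 1:3), chrom = 1, cM = 0:2)
  # 25 individuals: m1 has p = 0.04 (below 0.05), m2 p = 0.5, m3 p = 0.2
  g <- cbind(m1 = c(2, rep(0, 24)),
             m2 = rep(c(0, 2), length.out = 25),
             m3 = c(rep(2, 5), rep(0, 20)))
  rownames(g) <- paste0("i", 1:25)
  pan <- marker_panel(g, map, family = rep("A", 25))
  out <- impute_and_filter(pan, maf_min = 0.05)
  expect_false("m1" %in% colnames(out$genotypes))
  expect_setequal(colnames(out$genotypes), c("m2", "m3"))
  expect_equal(attr(out, "qc")$removed, "m1")

  # every retained marker satisfies the bound as computed post-imputation
  p <- out$allele_freq
  expect_true(all(pmin(p, 1 - p) >= 0.05))

  # idempotent
  out2 <- impute_and_filter(out, maf_min = 0.05)
  expect_identical(out2$genotypes, out$genotypes)

  # identity when nothing is missing and maf_min = 0
  out0 <- impute_and_filter(pan, maf_min = 0)
  expect_identical(out0$genotypes, pan$genotypes)

  # filtering everything is an error
  expect_error(impute_and_filter(pan, maf_min = 0.5), "no polymorphic")
})
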
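#' Configuration for a synthetic NAM population
#'
#' Builds and validates the configuration object consumed by
#' [simulate_founders()], [derive_rils()] and [simulate_phenotypes()].
#' Defaults emulate a soybean-style nested association mapping panel:
#' 40 biparental RIL families sharing one common parent, ~140 RILs per
#' family, ~4240 biallelic SNPs on 20 chromosomes, 6 environments over
#' 3 years, a 7:1 line-to-check augmented design, and a low-heritability
#' trait with additive, additive-by-additive, GxE and spatial variance.
#'
#' Heritability targets are fractions of the total plot-level phenotypic
#' variance, which is fixed at 1 squared trait unit; `gxe_sd` and
#' `spatial_gradient_sd` are standard deviations on the same trait scale,
#' so the residual variance is derived as
#' `1 - h2_additive - h2_epistatic - gxe_sd^2 - spatial_gradient_sd^2`.
#'
#' @param n_families Number of biparental families (each = common parent
#'   crossed to one alternate founder).
#' @param n_ril_per_family Recombinant inbred lines per family.
#' @param n_chrom,markers_per_chrom,chrom_length_cM Genome layout.
#' @param selfing_generations Rounds of single-seed-descent selfing after F1.
#' @param founder_maf_range Range (min, max) in (0, 0.5] from which the
#'   per-locus frequency of the counted allele among alternate founders is
#'   drawn.
#' @param n_qtl_additive,n_qtl_epistatic_pairs Number of additive QTL and
#'   of additive-by-additive interacting marker pairs.
#' @param h2_additive_target,h2_epistatic_target Target fractions of
#'   plot-level phenotypic variance; must sum to < 1.
#' @param gxe_sd SD of family-by-environment deviations (trait units).
#' @param spatial_gradient_sd SD of the smooth within-block field gradient.
#' @param n_environments,reps_per_env Trial structure; each replicate forms
#'   one field block.
#' @param check_ratio Lines per check plot (7 means a 7:1 augmented design).
#' @param missing_rate Fraction of genotype calls masked as missing.
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_families = 40L,
                       n_ril_per_family = 140L,
                       n_chrom = 20L,
                       markers_per_chrom = 212L,
                       chrom_length_cM = 100,
                       selfing_generations = 5L,
                       founder_maf_range = c(0.05, 0.5),
                       n_qtl_additive = 20L,
                       n_qtl_epistatic_pairs = 10L,
                       h2_additive_target = 0.15,
                       h2_epistatic_target = 0.08,
                       gxe_sd = 0.15,
                       spatial_gradient_sd = 0.2,
                       n_environments = 6L,
                       reps_per_env = 1L,
                       check_ratio = 7L,
                       missing_rate = 0.02,
                       seed = NULL) {
  cfg <- list(
    n_families = as.integer(n_families),
    n_ril_per_family = as.integer(n_ril_per_family),
    n_chrom = as.integer(n_chrom),
    markers_per_chrom = as.integer(markers_per_chrom),
    chrom_length_cM = as.numeric(chrom_length_cM),
    selfing_generations = as.integer(selfing_generations),
    founder_maf_range = as.numeric(founder_maf_range),
    n_qtl_additive = as.integer(n_qtl_additive),
    n_qtl_epistatic_pairs = as.integer(n_qtl_epistatic_pairs),
    h2_additive_target = as.numeric(h2_additive_target),
    h2_epistatic_target = as.numeric(h2_epistatic_target),
    gxe_sd = as.numeric(gxe_sd),
    spatial_gradient_sd = as.numeric(spatial_gradient_sd),
    n_environments = as.integer(n_environments),
    reps_per_env = as.integer(reps_per_env),
    check_ratio = as.integer(check_ratio),
    missing_rate = as.numeric(missing_rate),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(field, msg) {
    stop(sprintf("invalid sim_config field '%s': %s", field, msg), call. = FALSE)
  }
  if (cfg$n_families < 1L) stop_cfg("n_families", "must be >= 1")
  if (cfg$n_ril_per_family < 2L) stop_cfg("n_ril_per_family", "must be >= 2")
  if (cfg$markers_per_chrom < 2L) stop_cfg("markers_per_chrom", "must be >= 2")
  if (cfg$n_chrom < 1L) stop_cfg("n_chrom", "must be >= 1")
  if (cfg$chrom_length_cM <= 0) stop_cfg("chrom_length_cM", "must be > 0")
  if (cfg$selfing_generations < 0L) stop_cfg("selfing_generations", "must be >= 0")
  fr <- cfg$founder_maf_range
  if (length(fr) != 2L || any(fr <= 0) || any(fr > 0.5) || fr[1] > fr[2])
    stop_cfg("founder_maf_range", "must be (lo, hi) with 0 < lo <= hi <= 0.5")
  for (f in c("h2_additive_target", "h2_epistatic_target", "missing_rate")) {
    v <- cfg[[f]]
    if (v < 0 || v >= 1) stop_cfg(f, "must be a fraction in [0, 1)")
  }
  if (cfg$h2_additive_target + cfg$h2_epistatic_target >= 1)
    stop_cfg("h2_additive_target", "h2_additive_target + h2_epistatic_target must be < 1")
  if (cfg$gxe_sd < 0) stop_cfg("gxe_sd", "must be >= 0")
  if (cfg$spatial_gradient_sd < 0) stop_cfg("spatial_gradient_sd", "must be >= 0")
  if (cfg$n_environments < 1L) stop_cfg("n_environments", "must be >= 1")
  if (cfg$reps_per_env < 1L) stop_cfg("reps_per_env", "must be >= 1")
  if (cfg$check_ratio < 0L) stop_cfg("check_ratio", "must be >= 0 (0 disables checks)")
  invisible(cfg)
}

#' Genetic map for a simulated genome
#'
#' Markers are evenly spaced along each chromosome; physical coordinates
#' are synthesized from the cM position so that marker ids follow the
#' `Gm<chrom>_<bp>` convention (1-based bp).
#'
#' @param cfg A [sim_config()].
#' @return data.frame with columns marker, chrom, pos_bp, cM.
#' @export
make_genetic_map <- function(cfg) {
  m <- cfg$markers_per_chrom
  cm <- seq(0, cfg$chrom_length_cM, length.out = m)
  map <- do.call(rbind, lapply(seq_len(cfg$n_chrom), function(ch) {
    bp <- as.integer(round(cm * 1e5)) + 1L
    data.frame(
      marker = sprintf("Gm%02d_%d", ch, bp),
      chrom = ch, pos_bp = bp, cM = cm,
      stringsAsFactors = FALSE
    )
  }))
  rownames(map) <- NULL
  map
}

#' Simulate inbred founder genotypes
#'
#' One common parent plus `n_families` alternate founders, fully inbred
#' (codes 0/2). The counted allele is the alternate-founder allele: the
#' common parent carries code 0 everywhere and each alternate founder
#' carries code 2 at a locus with probability drawn from
#' `founder_maf_range`.
#'
#' @param cfg A [sim_config()].
#' @param map Optional genetic map; defaults to [make_genetic_map()].
#' @return A [marker_panel()] whose rows are the founders; the common
#'   parent is the first row (`family` = NA for all founders).
#' @export
simulate_founders <- function(cfg, map = NULL) {
  validate_sim_config(cfg)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (is.null(map)) map <- make_genetic_map(cfg)
  m <- nrow(map)
  p <- runif(m, cfg$founder_maf_range[1], cfg$founder_maf_range[2])
  alt <- matrix(2L * (matrix(runif(cfg$n_families * m), cfg$n_families, m) <
                        matrix(p, cfg$n_families, m, byrow = TRUE)),
                cfg$n_families, m)
  geno <- rbind(matrix(0L, 1L, m), alt)
  rownames(geno) <- c("CP000", sprintf("FP%03d", seq_len(cfg$n_families)))
  colnames(geno) <- map$marker
  marker_panel(geno, map, family = rep(NA_character_, nrow(geno)))
}

# One round of meiosis for a set of individuals stored as two haplotype
# matrices (n x m, allele indicators). `rfrac` holds the Haldane
# recombination fraction between locus j-1 and j; the first locus of each
# chromosome carries NA and restarts the chromatid choice at random.
.meiosis <- function(H1, H2, rfrac) {
  n <- nrow(H1); m <- ncol(H1)
  s <- integer(n)
  S <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    if (is.na(rfrac[j])) {
      s <- as.integer(runif(n) < 0.5)
    } else if (rfrac[j] > 0) {
      sw <- as.integer(runif(n) < rfrac[j])
      s <- (s + sw) %% 2L
    }
    S[, j] <- s
  }
  H1 * (1L - S) + H2 * S
}

# Haldane map function: d in cM -> recombination fraction.
haldane <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

.recomb_fractions <- function(map) {
  m <- nrow(map)
  r <- rep(NA_real_, m)
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    if (length(idx) > 1) {
      d <- diff(map$cM[idx])
      if (any(d < 0)) stop("map cM positions must be nondecreasing within chromosome")
      r[idx[-1]] <- haldane(d)
    }
  }
  r
}

#' Derive recombinant inbred lines from founders
#'
#' For each family the common parent is crossed to the alternate founder;
#' the F1 is then selfed for `selfing_generations` rounds by single-seed
#' descent, with meiosis simulated under the Haldane (no interference)
#' map function. Residual heterozygotes are coded 1.
#'
#' @param founders Panel from [simulate_founders()].
#' @param map Genetic map (defaults to the founder panel's map).
#' @param cfg The [sim_config()].
#' @return A [marker_panel()] of `n_families * n_ril_per_family` RILs with
#'   family labels `F01`, `F02`, ...
#' @export
derive_rils <- function(founders, map = NULL, cfg) {
  validate_sim_config(cfg)
  if (is.null(map)) map <- founders$map
  if (nrow(map) != ncol(founders$genotypes))
    stop("dimension error: map has ", nrow(map), " markers but founder panel has ",
         ncol(founders$genotypes))
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 1000003L)
  rfrac <- .recomb_fractions(map)
  m <- nrow(map)
  n <- cfg$n_ril_per_family
  common <- founders$genotypes[1L, ] / 2L
  out <- vector("list", cfg$n_families)
  for (f in seq_len(cfg$n_families)) {
    fdr <- founders$genotypes[f + 1L, ] / 2L
    H1 <- matrix(common, n, m, byrow = TRUE)
    H2 <- matrix(fdr, n, m, byrow = TRUE)
    for (g in seq_len(cfg$selfing_generations)) {
      G1 <- .meiosis(H1, H2, rfrac)
      G2 <- .meiosis(H1, H2, rfrac)
      H1 <- G1; H2 <- G2
    }
    out[[f]] <- H1 + H2
  }
  geno <- do.call(rbind, out)
  fam <- rep(sprintf("F%02d", seq_len(cfg$n_families)), each = n)
  ids <- paste0(fam, "-R", formatC(rep(seq_len(n), cfg$n_families),
                                   width = 3, flag = "0"))
  rownames(geno) <- ids
  colnames(geno) <- map$marker
  marker_panel(geno, map, family = fam)
}

# Smooth field gradient on a block: linear trend plus one low-frequency
# sinusoid, rescaled to the requested SD.
.spatial_surface <- function(row, col, sd_target) {
  if (sd_target <= 0 || length(row) < 2) return(rep(0, length(row)))
  zr <- (row - min(row)) / max(1, diff(range(row)))
  zc <- (col - min(col)) / max(1, diff(range(col)))
  b <- rnorm(2)
  fr <- runif(2, 0.5, 1.5); ph <- runif(1, 0, 2 * pi)
  s <- b[1] * zr + b[2] * zc + sin(2 * pi * (fr[1] * zr + fr[2] * zc) + ph)
  s <- s - mean(s)
  sds <- stats::sd(s)
  if (sds < 1e-12) return(rep(0, length(row)))
  s * sd_target / sds
}

#' Simulate multi-environment plot-level phenotypes
#'
#' Genetic values are built from additive QTL effects and
#' additive-by-additive pairwise products on centered marker codes,
#' rescaled so that the realized additive and epistatic variances hit the
#' configured fractions of a unit total plot variance. Plot values add an
#' environment main effect, a family-by-environment deviation, a smooth
#' spatial gradient per block, and i.i.d. residual noise. Checks (three
#' fixed founder genotypes) are interleaved at the configured
#' line-to-check ratio and are used downstream only for spatial
#' correction.
#'
#' @param panel RIL panel from [derive_rils()] (complete codes).
#' @param cfg The [sim_config()].
#' @param founders Founder panel; required when `check_ratio > 0`.
#' @param mu Grand mean (trait units).
#' @param trait_name Column name for the simulated trait.
#' @param residual_sd Override for the residual SD; `NULL` derives it from
#'   the variance budget (see [sim_config()]).
#' @return list with `plots` (plot-record data.frame) and `truth`
#'   (list recording QTL positions/effects, epistatic pairs, realized
#'   heritabilities, per-RIL genetic values and environment effects).
#' @export
simulate_phenotypes <- function(panel, cfg, founders = NULL, mu = 0,
                                trait_name = "y", residual_sd = NULL) {
  validate_sim_config(cfg)
  if (anyNA(panel$genotypes))
    stop("panel has missing codes; simulate phenotypes from the complete panel")
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 2000003L)
  hA <- cfg$h2_additive_target; hE <- cfg$h2_epistatic_target
  if (is.null(residual_sd)) {
    s2e <- 1 - hA - hE - cfg$gxe_sd^2 - cfg$spatial_gradient_sd^2
    if (s2e <= 0)
      stop("configuration error: variance targets (h2 + gxe_sd^2 + spatial_gradient_sd^2) sum to >= 1")
  } else {
    s2e <- residual_sd^2
  }

  geno <- panel$genotypes
  m <- ncol(geno); n <- nrow(geno)
  p <- colMeans(geno) / 2
  use_checks <- cfg$check_ratio > 0L
  if (use_checks && is.null(founders))
    stop("founders must be supplied when check_ratio > 0")
  if (use_checks) {
    ckrows <- unique(pmin(nrow(founders$genotypes), 1:3))
    ck_geno <- founders$genotypes[ckrows, , drop = FALSE]
    ck_ids <- paste0("CHK", seq_len(nrow(ck_geno)))
  }

  # additive QTL
  qtl <- sort(sample.int(m, min(cfg$n_qtl_additive, m)))
  a <- rnorm(length(qtl))
  Mc <- sweep(geno[, qtl, drop = FALSE], 2, 2 * p[qtl])
  gA <- drop(Mc %*% a)
  if (hA > 0 && stats::var(gA) > 0) {
    sc <- sqrt(hA / stats::var(gA)); a <- a * sc; gA <- gA * sc
  } else {
    a <- a * 0; gA <- gA * 0
  }

  # epistatic pairs (additive-by-additive products of centered codes)
  npair <- cfg$n_qtl_epistatic_pairs
  if (npair > 0) {
    pick <- replicate(npair, sort(sample.int(m, 2L)))
    ee <- rnorm(npair)
    Ecols <- vapply(seq_len(npair), function(k) {
      (geno[, pick[1, k]] - 2 * p[pick[1, k]]) *
        (geno[, pick[2, k]] - 2 * p[pick[2, k]])
    }, numeric(n))
    gE <- drop(Ecols %*% ee)
    if (hE > 0 && stats::var(gE) > 0) {
      sc <- sqrt(hE / stats::var(gE)); ee <- ee * sc; gE <- gE * sc
    } else {
      ee <- ee * 0; gE <- gE * 0
    }
    pairs <- data.frame(idx1 = pick[1, ], idx2 = pick[2, ], effect = ee)
  } else {
    gE <- numeric(n)
    pairs <- data.frame(idx1 = integer(0), idx2 = integer(0), effect = numeric(0))
  }
  g <- gA + gE
  names(g) <- rownames(geno)

  if (use_checks) {
    ckc <- sweep(ck_geno[, qtl, drop = FALSE], 2, 2 * p[qtl])
    g_ck <- drop(ckc %*% a)
    if (npair > 0) {
      ckE <- vapply(seq_len(npair), function(k) {
        (ck_geno[, pick[1, k]] - 2 * p[pick[1, k]]) *
          (ck_geno[, pick[2, k]] - 2 * p[pick[2, k]])
      }, numeric(nrow(ck_geno)))
      g_ck <- g_ck + drop(ckE %*% ee)
    }
    names(g_ck) <- ck_ids
  }

  # environment main effects, centered so the grand mean stays at mu
  env_eff <- rnorm(cfg$n_environments)
  env_eff <- env_eff - mean(env_eff)
  fams <- unique(panel$family)
  fe <- matrix(rnorm((length(fams) + 1L) * cfg$n_environments, 0, cfg$gxe_sd),
               length(fams) + 1L, cfg$n_environments,
               dimnames = list(c(fams, "CHK"), NULL))

  years <- paste0("Y", ceiling(seq_len(cfg$n_environments) /
                                 max(1, ceiling(cfg$n_environments / 3))))
  locs <- paste0("L", ((seq_len(cfg$n_environments) - 1L) %% 2L) + 1L)

  rows_out <- vector("list", cfg$n_environments * cfg$reps_per_env)
  k <- 0L
  for (e in seq_len(cfg$n_environments)) {
    for (b in seq_len(cfg$reps_per_env)) {
      ids <- sample(rownames(geno))
      if (use_checks && cfg$check_ratio > 0) {
        nck <- ceiling(length(ids) / cfg$check_ratio)
        ckv <- rep(ck_ids, length.out = nck)
        # interleave one check after every `check_ratio` lines
        full <- character(length(ids) + nck)
        pos_ck <- (seq_len(nck)) * (cfg$check_ratio + 1L)
        pos_ck <- pmin(pos_ck, length(full))
        full[pos_ck] <- ckv
        full[full == ""] <- ids
        ids <- full
      }
      np <- length(ids)
      ncols <- ceiling(sqrt(np))
      nrows <- ceiling(np / ncols)
      rr <- rep(seq_len(nrows), each = ncols)[seq_len(np)]
      cc <- rep(seq_len(ncols), nrows)[seq_len(np)]
      # serpentine layout
      flip <- rr %% 2L == 0L
      cc[flip] <- ncols + 1L - cc[flip]
      sp <- .spatial_surface(rr, cc, cfg$spatial_gradient_sd)
      isck <- grepl("^CHK", ids)
      fam_i <- ifelse(isck, "CHK", panel$family[match(ids, rownames(geno))])
      gval <- ifelse(isck,
                     if (use_checks) g_ck[ids] else 0,
                     g[ids])
      yv <- mu + gval + env_eff[e] + fe[cbind(match(fam_i, rownames(fe)), e)] + sp +
        rnorm(np, 0, sqrt(s2e))
      k <- k + 1L
      rows_out[[k]] <- data.frame(
        id = ids, family = fam_i, env = paste0("E", e),
        year = years[e], loc = locs[e],
        block = paste0("E", e, "B", b), row = rr, col = cc,
        is_check = isck, stringsAsFactors = FALSE
      )
      rows_out[[k]][[trait_name]] <- yv
    }
  }
  plots <- do.call(rbind, rows_out)
  rownames(plots) <- NULL

  truth <- list(
    qtl_positions = qtl,
    qtl_effects = a,
    epistatic_pairs = pairs,
    true_h2_additive = stats::var(gA),
    true_h2_epistatic = stats::var(gE),
    true_genetic_values = g,
    env_effects = env_eff,
    residual_var = s2e,
    mu = mu
  )
  list(plots = plots, truth = truth)
}

#' Mask genotype calls at random
#'
#' @param panel A [marker_panel()].
#' @param rate Fraction of calls set to missing.
#' @return The panel with `NA` codes planted.
#' @export
mask_genotypes <- function(panel, rate) {
  if (rate <= 0) return(panel)
  geno <- panel$genotypes
  nmiss <- round(length(geno) * rate)
  if (nmiss > 0) geno[sample.int(length(geno), nmiss)] <- NA
  marker_panel(geno, panel$map, panel$family)
}

#' Simulate a complete synthetic NAM study
#'
#' Convenience wrapper: founders, RILs, phenotypes and missing-call
#' masking, all driven by one seeded configuration. Seeds for the three
#' stochastic stages are derived deterministically from `cfg$seed`, so a
#' given configuration is bit-reproducible end to end.
#'
#' @param cfg A [sim_config()].
#' @inheritParams simulate_phenotypes
#' @return list with `panel` (masked per `missing_rate`), `panel_complete`,
#'   `founders`, `map`, `plots`, `truth`.
#' @export
simulate_nam <- function(cfg, mu = 0, trait_name = "y", residual_sd = NULL) {
  validate_sim_config(cfg)
  map <- make_genetic_map(cfg)
  founders <- simulate_founders(cfg, map)
  rils <- derive_rils(founders, map, cfg)
  ph <- simulate_phenotypes(rils, cfg, founders = founders, mu = mu,
                            trait_name = trait_name, residual_sd = residual_sd)
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 3000017L)
  masked <- mask_genotypes(rils, cfg$missing_rate)
  list(panel = masked, panel_complete = rils, founders = founders,
       map = map, plots = ph$plots, truth = ph$truth)
}
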
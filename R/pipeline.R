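# Pipeline orchestration: simulate -> qc -> merit -> kernels -> varcomp
# -> corr -> gwas -> cv, driven by a YAML (or list) configuration with
# one top-level seed. Per-stage seeds are derived deterministically so a
# config + seed pair reproduces every stochastic output bit-exactly.

.stage_seed <- function(seed, stage) {
  offs <- c(simulate = 1L, qc = 2L, merit = 3L, kernels = 4L,
            varcomp = 5L, corr = 6L, gwas = 7L, cv = 8L)
  (seed + offs[[stage]] * 1000003L) %% .Machine$integer.max
}

.default_config <- function() {
  list(
    stages = c("simulate", "qc", "merit", "kernels", "varcomp", "gwas", "cv"),
    trait = "y",
    simulate = list(n_families = 2, n_ril_per_family = 50, n_chrom = 4,
                    markers_per_chrom = 50, n_environments = 1,
                    chrom_length_cM = 100),
    qc = list(maf_min = 0.05),
    merit = list(window = c(1, 1)),
    gwas = list(methods = "mlm", rfr = list(n_trees = 500, mtry = 10,
                                            n_perm = 50),
                wgr = list(iters = 5000, burnin = 500)),
    cv = list(schemes = "across_family", models = "GBLUP",
              folds = 5, reps = 2)
  )
}

validate_run_config <- function(config) {
  if (is.null(config$stages) || !length(config$stages))
    stop("run config error: 'stages' must list at least one stage")
  known <- c("simulate", "qc", "merit", "kernels", "varcomp", "corr",
             "gwas", "cv")
  bad <- setdiff(config$stages, known)
  if (length(bad))
    stop("run config error: unknown stage(s): ", paste(bad, collapse = ", "))
  needs_pheno <- intersect(c("merit"), config$stages)
  if (length(needs_pheno) && !("simulate" %in% config$stages) &&
      is.null(config$pheno_path))
    stop("run config error: merit stage enabled but no phenotype source ",
         "('simulate' stage or pheno_path)")
  needs_geno <- intersect(c("qc", "kernels", "gwas", "cv"), config$stages)
  if (length(needs_geno) && !("simulate" %in% config$stages) &&
      is.null(config$geno_path))
    stop("run config error: genomic stages enabled but no genotype source")
  invisible(config)
}

#' Run the NAM analysis pipeline
#'
#' Executes the enabled stages in dependency order, writing each stage's
#' outputs plus a log and a manifest (config, seed, versions, file
#' checksums, stage timings) to the run directory.
#'
#' @param config Path to a YAML file or a configuration list. See
#'   the package vignette for the schema; unspecified fields fall back
#'   to a small demo configuration.
#' @param out_dir Run directory (created if needed).
#' @param seed Integer seed; overrides `config$seed`.
#' @return Invisibly, a list of in-memory stage results; side effect:
#'   files under `out_dir`.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("namqg_run_"),
                         seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- .default_config()
  if (is.null(config)) config <- base
  for (nm in names(base)) if (is.null(config[[nm]])) config[[nm]] <- base[[nm]]
  if (!is.null(seed)) config$seed <- seed
  if (is.null(config$seed)) config$seed <- 1L
  validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  logmsg <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S"), paste0(...), "\n",
        file = logf, append = TRUE)
  }
  timings <- list()
  res <- list()
  trait <- config$trait

  run_stage <- function(name, fn) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    t0 <- proc.time()[3]
    out <- tryCatch(fn(), error = function(e) {
      logmsg("stage ", name, " FAILED: ", conditionMessage(e))
      stop("pipeline halted in stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[3] - t0, 2)
    logmsg("stage ", name, " done in ", timings[[name]], "s")
    out
  }

  res$simulate <- run_stage("simulate", function() {
    cfg <- do.call(sim_config, c(config$simulate,
                                 list(seed = .stage_seed(config$seed,
                                                         "simulate"))))
    sim <- simulate_nam(cfg, trait_name = trait)
    write_panel(sim$panel,
                file.path(out_dir, "genotypes.tsv"),
                file.path(out_dir, "map.tsv"),
                file.path(out_dir, "families.tsv"))
    utils::write.csv(sim$plots, file.path(out_dir, "phenotypes.csv"),
                     row.names = FALSE)
    tr <- sim$truth
    tr$true_genetic_values <- as.list(tr$true_genetic_values)
    jsonlite::write_json(tr, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    sim
  })

  panel <- if (!is.null(res$simulate)) res$simulate$panel else
    read_panel(config$geno_path, config$map_path, config$fam_path)
  plots <- if (!is.null(res$simulate)) res$simulate$plots else
    if (!is.null(config$pheno_path))
      utils::read.csv(config$pheno_path, stringsAsFactors = FALSE) else NULL

  res$qc <- run_stage("qc", function() {
    out <- impute_and_filter(panel, config$qc$maf_min)
    qc <- attr(out, "qc")
    jsonlite::write_json(qc[c("n_imputed", "n_removed", "n_retained")],
                         file.path(out_dir, "qc.json"), auto_unbox = TRUE)
    out
  })
  if (!is.null(res$qc)) panel <- res$qc

  res$merit <- run_stage("merit", function() {
    fit <- fit_merit(plots, trait, window = config$merit$window)
    utils::write.csv(fit$table, file.path(out_dir, "merit.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(varcomp = as.list(fit$varcomp), H = fit$H,
                              r = fit$r, converged = fit$converged),
                         file.path(out_dir, "merit_varcomp.json"),
                         auto_unbox = TRUE, digits = NA)
    fit
  })

  yv <- if (!is.null(res$merit)) deregressed(res$merit) else NULL
  if (!is.null(yv)) {
    keep <- intersect(names(yv), rownames(panel$genotypes))
    yv <- yv[keep]
  }

  res$kernels <- run_stage("kernels", function() {
    ids <- if (!is.null(yv)) names(yv) else rownames(panel$genotypes)
    M <- center_markers(subset_panel(panel, individuals = ids))
    ks <- build_kernels(M)
    saveRDS(ks, file.path(out_dir, "kernels.rds"))
    writeLines(ids, file.path(out_dir, "kernel_ids.txt"))
    ks
  })

  res$varcomp <- run_stage("varcomp", function() {
    if (is.null(yv)) stop("varcomp needs merit output")
    fam <- panel$family[match(names(yv), rownames(panel$genotypes))]
    fit <- fit_g2a(yv, groups = fam, panel = panel)
    utils::write.csv(fit$by_family, file.path(out_dir, "varcomp.csv"),
                     row.names = FALSE)
    fit
  })

  res$corr <- run_stage("corr", function() {
    if (is.null(plots) || is.null(panel)) stop("corr needs plots and panel")
    yrs <- sort(unique(plots$year))
    if (length(yrs) < 2) stop("stability correlation needs >= 2 years")
    pairs <- utils::combn(yrs, 2, simplify = FALSE)
    out <- lapply(pairs, function(pr) {
      f1 <- fit_merit(plots[plots$year == pr[1], , drop = FALSE], trait,
                      window = config$merit$window)
      f2 <- fit_merit(plots[plots$year == pr[2], , drop = FALSE], trait,
                      window = config$merit$window)
      y1 <- deregressed(f1); y2 <- deregressed(f2)
      ids <- intersect(names(y1), names(y2))
      ids <- intersect(ids, rownames(panel$genotypes))
      M <- center_markers(subset_panel(panel, individuals = ids))
      K <- build_kernels(M)$K
      bf <- fit_bivariate(y1[ids], y2[ids], K)
      data.frame(year_i = pr[1], year_j = pr[2], rho_psi = bf$rho_psi,
                 rho_blup = bf$rho_blup, degenerate = bf$degenerate)
    })
    tab <- do.call(rbind, out)
    utils::write.csv(tab, file.path(out_dir, "stability_corr.csv"),
                     row.names = FALSE)
    tab
  })

  res$gwas <- run_stage("gwas", function() {
    if (is.null(yv)) stop("gwas needs merit output")
    sp <- subset_panel(panel, individuals = names(yv))
    gseed <- .stage_seed(config$seed, "gwas")
    scans <- list()
    meths <- config$gwas$methods
    if (any(meths %in% c("mlm", "all")))
      scans$MLM <- scan_mlm(yv, sp)
    if (any(meths %in% c("wgr", "all")))
      scans$WGR <- scan_bayescpi(yv, sp, iters = config$gwas$wgr$iters,
                                 burnin = config$gwas$wgr$burnin,
                                 seed = gseed)
    if (any(meths %in% c("rfr", "all")))
      scans$RFR <- scan_rfr(yv, sp, n_trees = config$gwas$rfr$n_trees,
                            mtry = config$gwas$rfr$mtry,
                            n_perm = config$gwas$rfr$n_perm, seed = gseed)
    for (nm in names(scans))
      utils::write.table(scans[[nm]]$table,
                         file.path(out_dir, paste0("gwas_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(scans) > 1)
      utils::write.table(consensus_table(scans),
                         file.path(out_dir, "gwas_consensus.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    scans
  })

  res$cv <- run_stage("cv", function() {
    if (is.null(yv)) stop("cv needs merit output")
    sp <- subset_panel(panel, individuals = names(yv))
    cseed <- .stage_seed(config$seed, "cv")
    out <- list()
    for (sc in config$cv$schemes)
      for (md in config$cv$models)
        out[[paste(sc, md, sep = ".")]] <-
          cross_validate(yv, sp, scheme = sc, model = md,
                         folds = config$cv$folds, reps = config$cv$reps,
                         seed = cseed)
    tab <- do.call(rbind, lapply(out, function(x) x$table))
    utils::write.csv(tab, file.path(out_dir, "cv.csv"), row.names = FALSE)
    summ <- lapply(out, function(x) list(mean_pa = x$mean_pa,
                                         sd_pa = x$sd_pa))
    jsonlite::write_json(summ, file.path(out_dir, "cv_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    out
  })

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "manifest.json"))
  manifest <- list(
    package = "namqg",
    version = as.character(utils::packageVersion("namqg")),
    r_version = R.version.string,
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    timings = timings,
    files = as.list(tools::md5sum(files[!dir.exists(files)]))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logmsg("pipeline complete")
  invisible(res)
}
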
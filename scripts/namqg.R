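#!/usr/bin/env Rscript

# Thin command-line wrapper over namqg::run_pipeline():
#   Rscript scripts/namqg.R <stage|all> --config cfg.yaml --out DIR --seed N
# Stages: simulate qc merit kernels varcomp corr gwas cv all

suppressMessages({
  library(namqg)
  library(optparse)
})

args <- commandArgs(trailingOnly = TRUE)
stage <- if (length(args) && !startsWith(args[1], "-")) args[1] else "all"
rest <- if (length(args) && !startsWith(args[1], "-")) args[-1] else args

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--out", type = "character", default = "namqg_run"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--log-level", type = "character", default = "info",
              dest = "log_level")
)), args = rest)

config <- if (is.null(opts$config)) NULL else yaml::read_yaml(opts$config)
if (stage != "all") {
  if (is.null(config)) config <- list()
  config$stages <- strsplit(stage, ",")[[1]]
}

run_pipeline(config, out_dir = opts$out, seed = opts$seed)
cat("run complete:", normalizePath(opts$out), "\n")
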
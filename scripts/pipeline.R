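#!/usr/bin/env Rscript

# Thin command-line wrapper around perturbcircuit::run_pipeline().
#
# Usage: Rscript scripts/pipeline.R [--config cfg.yaml] [--out DIR] [--seed N]

suppressPackageStartupMessages({
  library(optparse)
  library(perturbcircuit)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML configuration (default: built-in demo settings)"),
  make_option("--out", type = "character", default = NULL,
              help = "output directory (overrides the config)"),
  make_option("--seed", type = "integer", default = NULL,
              help = "master seed (overrides the config)")
)))

config <- if (is.null(opts$config)) pipeline_config() else pipeline_config(opts$config)
if (!is.null(opts$out)) config$output_dir <- opts$out
if (!is.null(opts$seed)) config$master_seed <- opts$seed
invisible(run_pipeline(config))
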
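#!/usr/bin/env Rscript

# Thin command-line wrapper over occupet::run_pipeline().
#
# Usage: Rscript scripts/run_pipeline.R --config run.yaml --outdir out \
#          [--seed INT] [--voxel] [--quiet]

suppressMessages({
  library(optparse)
  library(occupet)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character"),
  make_option("--outdir", type = "character", default = "occupet_run"),
  make_option("--seed", type = "integer", default = NULL),
  make_option("--voxel", action = "store_true", default = FALSE),
  make_option("--quiet", action = "store_true", default = FALSE)
)))

if (is.null(opts$config)) stop("--config is required")
config <- yaml::read_yaml(opts$config)
if (!is.null(opts$seed)) config$seed <- opts$seed
if (isTRUE(opts$voxel)) config$voxel <- TRUE

status <- tryCatch({
  run_pipeline(config, opts$outdir, quiet = opts$quiet)
  0L
}, error = function(e) {
  message("pipeline failed: ", conditionMessage(e))
  1L
})
quit(status = status)
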
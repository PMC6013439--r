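#!/usr/bin/env Rscript
# Thin command-line wrapper around tidalcarbon::run_pipeline().
#   Rscript scripts/tidalcarbon.R run --config config.yaml [--out report/]

suppressPackageStartupMessages({
  library(optparse)
  library(tidalcarbon)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 || args[1] != "run") {
  cat("usage: Rscript scripts/tidalcarbon.R run [--config config.yaml] [--out dir]\n")
  quit(status = if (length(args) && args[1] %in% c("-h", "--help")) 0 else 1)
}

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--out", type = "character", default = "tidalcarbon-report")
)), args = args[-1])

config <- if (is.null(opts$config)) pipeline_config() else opts$config
run_pipeline(config, out_dir = opts$out)
cat("report written to", opts$out, "\n")
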
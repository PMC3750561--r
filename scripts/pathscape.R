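#!/usr/bin/env Rscript
# Thin command-line front end over the pathscape package.
#
#   Rscript scripts/pathscape.R run --config cfg.yaml
#   Rscript scripts/pathscape.R simulate --out dir [--seed N] [--n-genes N]
#
# `run` executes the full analysis described by a YAML config (see
# ?read_run_config for the fields). `simulate` writes a small demonstration
# cohort with planted subgroups in the exact formats `run` consumes.

suppressPackageStartupMessages({
  library(optparse)
  library(pathscape)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 || !args[1] %in% c("run", "simulate")) {
  cat("usage: pathscape.R <run|simulate> [options]\n")
  quit(status = 1)
}
cmd <- args[1]

if (cmd == "run") {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--config", type = "character"))), args = args[-1])
  if (is.null(opts$config)) stop("run needs --config <yaml>")
  run_pipeline(opts$config)
} else {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--out", type = "character"),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--n-genes", type = "integer", default = 1000L,
                dest = "n_genes"))), args = args[-1])
  if (is.null(opts$out)) stop("simulate needs --out <dir>")
  gs <- generate_genesets(12, c(10, 40), opts$n_genes, 0, seed = opts$seed)
  des <- cohort_design(
    n_genes = opts$n_genes,
    cancers = list(
      list(label = "CA", subgroups = list(
        list(size = 25, aberrations = c(SET001 = "ENRICHED",
                                        SET002 = "ENRICHED"), hazard = 3),
        list(size = 25, aberrations = c(SET003 = "DEPLETED")))),
      list(label = "CB", subgroups = list(
        list(size = 25, aberrations = c(SET004 = "ENRICHED")),
        list(size = 25, aberrations = setNames(character(0), character(0)))))),
    delta = 1, sigma = 1, n_duplicates = 2L)
  co <- generate_cohort(des, gs, seed = opts$seed)
  sv <- generate_survival(co$truth, censoring_fraction = 0.2,
                          seed = opts$seed)
  write_cohort(co, gs, opts$out, survival = sv)
  cat("wrote synthetic cohort to ", opts$out, "\n", sep = "")
}
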
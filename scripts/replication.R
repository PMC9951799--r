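#!/usr/bin/env Rscript

# Optional replication driver: runs the complete analysis on a user-supplied
# compiled dataset and phylogeny (e.g. a published supplementary data table
# mapped to this package's study-table schema; see ?read_study_table for the
# required columns).
#
#   Rscript scripts/replication.R --data <table.csv> --tree <tree.nwk> \
#       --out <dir> [--seed <int>] [--chains 4] [--iter 2000]
#
# Prints the analyzed-record bookkeeping, the intercept-model component
# intercepts, the three hypothesis contrasts with 95% intervals, the
# variance decomposition, model comparison, and bias diagnostics.

suppressPackageStartupMessages(library(allelometa))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) return(args[i + 1])
  default
}
data_path <- get_arg("--data")
tree_path <- get_arg("--tree")
if (is.null(data_path) || is.null(tree_path)) {
  stop("usage: Rscript scripts/replication.R --data <csv> --tree <newick> ",
       "--out <dir> [--seed <int>]")
}

config <- run_config(
  input = data_path,
  tree = tree_path,
  out_dir = get_arg("--out", "replication_out"),
  seed = as.integer(get_arg("--seed", "1")),
  chains = as.integer(get_arg("--chains", "4")),
  iter = as.integer(get_arg("--iter", "2000")),
  warmup = as.integer(get_arg("--iter", "2000")) %/% 2)

report <- run_all(config)
print(report)

cat("\nVariance decomposition (intercept model):\n")
print(report$decomposition[, c("component", "percent")], row.names = FALSE)
cat("\nModel comparison (full vs intercept):\n")
print(report$comparison, row.names = FALSE)
cat(sprintf("\nEgger intercept: %.3f [%.3f, %.3f]\n",
            report$egger$intercept, report$egger$intercept_ci[1],
            report$egger$intercept_ci[2]))
if (!is.null(report$year_trend)) {
  cat(sprintf("Year-trend slope: %.3f [%.3f, %.3f]\n",
              report$year_trend$slope, report$year_trend$slope_ci[1],
              report$year_trend$slope_ci[2]))
}
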
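#!/usr/bin/env Rscript
# Thin command-line wrapper over the package's reporting functions.
#
# Usage:
#   Rscript scripts/run_model.R run      [--config F] [--age A] [--trials N]
#                                        [--seed S] [--life-table F] [--out D]
#   Rscript scripts/run_model.R validate [same flags]
#   Rscript scripts/run_model.R dsa      [same flags]
#   Rscript scripts/run_model.R psa      [same flags] [--sims K]

suppressPackageStartupMessages(library(osteosim))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) {
  stop("usage: run_model.R {run|validate|dsa|psa} [flags]", call. = FALSE)
}
cmd <- args[1]
flags <- args[-1]
get_flag <- function(name, default = NULL) {
  i <- which(flags == name)
  if (length(i) == 1 && i < length(flags)) flags[i + 1] else default
}

config <- get_flag("--config")
age <- get_flag("--age")
if (!is.null(age)) age <- as.integer(age)
trials <- get_flag("--trials")
if (!is.null(trials)) trials <- as.integer(trials)
seed <- get_flag("--seed")
if (!is.null(seed)) seed <- as.integer(seed)
sims <- as.integer(get_flag("--sims", "1000"))
out <- get_flag("--out", ".")
lt_path <- get_flag("--life-table")
lt <- if (is.null(lt_path)) NULL else load_life_table(lt_path)

status <- tryCatch({
  switch(cmd,
    run = cmd_run(config, age, out, trials, seed, lt),
    validate = cmd_validate(config, age, out, trials, seed, lt),
    dsa = cmd_dsa(config, age, out, trials, seed, lt),
    psa = cmd_psa(config, age, out, n_sims = sims, n_trials = trials,
                  seed = seed, life_table = lt),
    stop("unknown command '", cmd, "'", call. = FALSE)
  )
  0L
}, error = function(e) {
  message("error: ", conditionMessage(e))
  1L
})
quit(status = status)
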
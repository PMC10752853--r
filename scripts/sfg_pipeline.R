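#!/usr/bin/env Rscript

# Thin command-line wrapper over the sfgci package.
#
#   Rscript scripts/sfg_pipeline.R synthesize     --out DIR [--seed S] [--n-trials N]
#   Rscript scripts/sfg_pipeline.R simulate-study --out DIR [--seed S] [--n-subjects N]

suppressPackageStartupMessages({
  library(sfgci)
  library(optparse)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 || !args[1] %in% c("synthesize", "simulate-study")) {
  stop("usage: sfg_pipeline.R {synthesize|simulate-study} --out DIR [options]",
       call. = FALSE)
}
command <- args[1]

opts <- parse_args(
  OptionParser(option_list = list(
    make_option("--out", type = "character", default = "sfg_output"),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--n-trials", type = "integer", default = 120L,
                dest = "n_trials"),
    make_option("--n-subjects", type = "integer", default = 47L,
                dest = "n_subjects")
  )),
  args = args[-1]
)

if (command == "synthesize") {
  man <- cmd_synthesize(opts$out, n_trials = opts$n_trials, seed = opts$seed)
  cat(sprintf("wrote %d stimuli and manifest to %s\n", nrow(man), opts$out))
} else {
  fit <- cmd_simulate_study(opts$out, n_subjects = opts$n_subjects,
                            seed = opts$seed)
  print(fit)
  cat(sprintf("analysis bundle written to %s\n", opts$out))
}
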
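#!/usr/bin/env Rscript
# Stage 7: assemble the run summary (anchor checks, fit waterfall, profile
# intervals, sensitivity ranking, schedule comparison) from the tables the
# earlier stages wrote, into results/report.md.

suppressPackageStartupMessages(library(hepstat3))
cfg <- read_config(if (file.exists("analysis/config.yaml"))
  "analysis/config.yaml" else NULL)
out <- cfg$out_dir
rd <- function(...) read_dataset(file.path(out, ...))
fmt <- function(df) paste(capture.output(print(df, row.names = FALSE)),
                          collapse = "\n")

sink(file.path(out, "report.md"))
cat("# Run summary (seed ", cfg$seed, ", mode ", cfg$mode, ")\n\n", sep = "")

cat("## Anchor checks\n\n```\n",
    fmt(rd("data", "anchor_values.tsv")), "\n```\n\n", sep = "")

wf <- rd("fits", "waterfall.tsv")
cat("## Fit waterfall (gene-module multi-start)\n\n```\n",
    fmt(do.call(rbind, lapply(split(wf, wf$gene), utils::head, 3))),
    "\n```\n\n", sep = "")

cat("## Profile-likelihood 95% intervals\n\n```\n",
    fmt(rd("profiles", "intervals.tsv")), "\n```\n\n", sep = "")

s <- rd("lpsa.tsv")
cat("## Sensitivity (top 10 by |mean|)\n\n```\n",
    fmt(utils::head(s[, c("parameter", "S_mean")], 10)),
    "\n```\n\n", sep = "")

sch <- rd("dosing", "schedule_evaluation.tsv")
cat("## Schedule comparison (normalized integrated response)\n\n```\n",
    fmt(sch[, c("schedule", "gene", "integral_normalized")]),
    "\n```\n\n", sep = "")

cat("## Physiology: liver signal inversion\n\n```\n",
    fmt(rd("physiology", "liver_inversion.tsv")), "\n```\n", sep = "")
sink()
message("wrote ", file.path(out, "report.md"))
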
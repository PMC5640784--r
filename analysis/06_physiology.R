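#!/usr/bin/env Rscript
# Stage 6: physiology mapping. Fit the 4PL ex-vivo calibration curve, invert
# the liver phospho-STAT3 bead-array signals to local-equivalent IL-6
# intervals, and convert to mouse-IL-6 potency.

suppressPackageStartupMessages(library(hepstat3))
cfg <- read_config(if (file.exists("analysis/config.yaml"))
  "analysis/config.yaml" else NULL)
dir.create(file.path(cfg$out_dir, "physiology"), recursive = TRUE,
           showWarnings = FALSE)

ref <- reference_parameters(mode = cfg$mode)
exvivo <- read_dataset(file.path(cfg$out_dir, "data", "exvivo.tsv"))
liver <- read_dataset(file.path(cfg$out_dir, "data", "liver.tsv"))

fit <- fit_hill4(exvivo$dose, exvivo$signal)
print(fit)
write_dataset(data.frame(parameter = c("y_min", "y_max", "ec50", "hill"),
                         estimate = c(fit$y_min, fit$y_max, fit$ec50,
                                      fit$hill),
                         reference = unname(ref$hill)),
              file.path(cfg$out_dir, "physiology", "hill_fit.tsv"))

rows <- list()
for (cond in unique(liver$condition)) {
  peak_t <- if (cond == "LPS") 1 else 2
  x <- liver[liver$condition == cond & liver$time_h == peak_t, ]
  inv <- invert_signal(fit, mean(x$value),
                       stats::sd(x$value) / sqrt(nrow(x)))
  rows[[cond]] <- data.frame(
    condition = cond, time_h = peak_t,
    signal_mean = mean(x$value),
    il6_lower = inv$lower, il6_upper = inv$upper,
    il6_midpoint = inv$midpoint,
    il6_midpoint_mouse = round_half_up(
      potency_convert(inv$midpoint, "human_to_mouse"), 1),
    censored_high = inv$censored_high)
  message(sprintf(
    "%s: local-equivalent hIL-6 %.1f (%.1f-%.1f ng/mL)%s",
    cond, inv$midpoint, inv$lower, inv$upper,
    if (inv$censored_high) " [upper censored]" else ""))
}
write_dataset(do.call(rbind, rows),
              file.path(cfg$out_dir, "physiology", "liver_inversion.tsv"))
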
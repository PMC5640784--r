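#!/usr/bin/env Rscript
# Stage 1: generate the synthetic datasets (calibration suite, in-vivo serum
# and liver tables, ex-vivo calibration curve) and write them to results/data.

suppressPackageStartupMessages(library(hepstat3))
cfg <- read_config(if (file.exists("analysis/config.yaml"))
  "analysis/config.yaml" else NULL)
dir.create(file.path(cfg$out_dir, "data"), recursive = TRUE,
           showWarnings = FALSE)

ref <- reference_parameters(mode = cfg$mode)
net <- build_reference_network(ref)

message("verifying reference anchors ...")
anchors <- verify_anchors(ref, network = net)
write_dataset(
  data.frame(anchor = names(anchors), value = unlist(anchors)),
  file.path(cfg$out_dir, "data", "anchor_values.tsv"))

message("generating calibration suite (seed ", cfg$seed, ") ...")
suite <- generate_suite(ref, seed = cfg$seed, network = net)
write_dataset(suite, file.path(cfg$out_dir, "data", "suite.tsv"))

invivo <- generate_invivo(ref, n = 6, seed = cfg$seed)
write_dataset(invivo$serum, file.path(cfg$out_dir, "data", "serum.tsv"))
write_dataset(invivo$liver, file.path(cfg$out_dir, "data", "liver.tsv"))

exvivo <- generate_exvivo_curve(ref, seed = cfg$seed)
write_dataset(exvivo, file.path(cfg$out_dir, "data", "exvivo.tsv"))

write_params(reference_param_vector(ref),
             file.path(cfg$out_dir, "data", "reference_parameters.yaml"))
message("wrote ", nrow(suite), " suite records to ",
        file.path(cfg$out_dir, "data"))
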
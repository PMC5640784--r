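# Shared fixtures, built once per test run.
REF <- reference_parameters()
NET <- build_reference_network(REF)
PVEC <- reference_param_vector(REF)
CORE_NET <- build_core_model(REF$core, REF$compartments, REF$fixed_totals)

# total STAT3 amount (molecule-equivalent nM * pL) along a trajectory
stat3_amount <- function(traj) {
  Vc <- traj$compartments$cytoplasm$volume_pl
  Vn <- traj$compartments$nucleus$volume_pl
  (traj$states[, "STAT3"] + traj$states[, "pSTAT3"]) * Vc +
    traj$states[, "nSTAT3"] * Vn
}
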
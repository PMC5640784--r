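seed: 1
mode: mouse
out_dir: results
cap: 500
max_doses: 3
perturbation: 0.5
il6: 100
horizon: 24
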
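# full-pipeline config for `fibrenet run --config example_run.yaml`
fixture:
  kind: wedge
  dims: [60, 40, 16]
  thickness: [2, 14]
model: both
c_values: [0.4, 0.7, 1.0]
r: 7
cutoff: 2
ddm:
  tau: 10
metrics:
  r_tilde: 5
  eps: 10
n_networks: 50
n_circuits: 200
sigma: 5
seed: 1
out_dir: fibrenet_out
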
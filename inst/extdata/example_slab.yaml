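# fixture spec for `fibrenet synth --config example_slab.yaml --out slab`
kind: slab
dims: [40, 30, 4]
thickness: 4
fibre_angle: 0
seed: 1
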
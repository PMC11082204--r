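# Default end-to-end run: small synthetic study at full patch geometry.
scene:
  n_scenes: 6
  preset: easy
  height: 256
  width: 256
  n_bands: 150
pipeline:
  target_size: 256
  patch_size: 64
  stride: 32
  rot_threshold: 0.10
  bg_threshold: 0.50
  ratio: [2, 1, 1]
  augment_eval: true
model:
  variant: DBSACaps
  routing_iters: 3
train:
  learning_rate: 5.0e-6
  weight_decay: 1.0e-6
  batch_size: 16
  epochs: 100
  microbatch: 2
seed: 1
out: dbsacaps_run
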
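# Desk-scale depth training profile (single CPU, synthetic scenes)
profile: desk
stage: depth
model:
  input_size: [64, 64]
  patch: 16
  embed_dim: 64
  n_blocks: 4
  n_heads: 4
  dec_ch: 32
  head_ch: 16
  depth_scale: 40
  loss: l1
train:
  optimizer: adam
  lr: 2.0e-3
  schedule: cosine
  lr_min: 2.0e-4
  steps: 500
  batch_size: 4
  seed: 1
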
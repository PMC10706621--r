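# Desk-scale fusion training profile (single CPU, synthetic scenes)
profile: desk
stage: fusion
model:
  input_size: [32, 32]
  channels: [8, 16, 32, 64, 128]
  head_dim: 64
  streams: rgbd
  attention: true
  multiscale: true
  depth_norm: fixed
  depth_scale: 35
train:
  optimizer: adam
  lr: 5.0e-3
  schedule: exponential
  decay: 0.98
  steps: 500
  batch_size: 8
  augment:
    horizontal_flip: true
  seed: 1
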
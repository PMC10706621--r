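# Full-scale fusion training profile. The full-scale reference recipe: inputs
# resized to 336 x 448, center crop + random horizontal flip augmentation,
# ResNet101-scale backbone channels, a 2048-wide shared head, Adam at 5e-5
# with exponential decay 0.98 per epoch, 150 epochs, batch size 8.
# Not exercised by the test suite.
profile: gpu
stage: fusion
model:
  input_size: [336, 448]
  channels: [64, 256, 512, 1024, 2048]
  head_dim: 2048
  streams: rgbd
  attention: true
  multiscale: true
  depth_norm: fixed
  depth_scale: 100
train:
  optimizer: adam
  lr: 5.0e-5
  schedule: exponential
  decay: 0.98
  epochs: 150
  batch_size: 8
  augment:
    center_crop: true
    horizontal_flip: true
  seed: 1
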
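# Full-scale depth training profile. The full-scale reference recipe: inputs
# resized to a 384-pixel long side with random 384 square crops, Adam at
# 1e-5 cosine-annealed to 1e-6, 60 epochs, batch size 8, ImageNet-style
# pretrained encoder init where available. Not exercised by the test suite.
profile: gpu
stage: depth
model:
  input_size: [384, 384]
  patch: 16
  embed_dim: 768
  n_blocks: 12
  n_heads: 12
  dec_ch: 256
  head_ch: 128
  depth_scale: 100
  loss: l1
train:
  optimizer: adam
  lr: 1.0e-5
  schedule: cosine
  lr_min: 1.0e-6
  epochs: 60
  batch_size: 8
  augment:
    random_square_crop: 384
  seed: 1
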
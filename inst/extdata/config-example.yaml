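# Example pipeline configuration for the rcnet command-line driver.
# Sections map onto the package constructors: synth -> synthConfig(),
# split -> splitConfig(), encoder -> encoderConfig(), train -> trainConfig(),
# loss -> lossConfig(). Seeds are injected from --seed and fanned out per
# stage, so they are not set here.
synth:
  templates: 4
  perTemplate: 10
  maxDecor: 3
  clusters: 6
  perCluster: 10
  embeddingDim: 64
  seqLength: 60
  density: 0.05
metric: rcmcs
split:
  bounds: [0.4, 0.6, 0.8, 1.0]
  entity: reaction
  testFraction: 0.2
  cvFolds: 3
encoder:
  variant: rc_aggregated
  M: 4
  hidden: 24
  d: 24
train:
  epochs: 10
  batchSize: 64
  lr: 0.002
loss:
  m: 3
  p: 3
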
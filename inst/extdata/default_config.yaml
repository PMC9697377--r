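# Default run configuration. Any field may be overridden by a user config
# file or command-line flags; the resolved result is saved with every run.
seed: 0
backbone:
  depth: tiny            # tiny | resnet18 | resnet50
  deformable: true
  deformable_stages: [C4, C5]
  pretrained: false
neck:
  channels: 32
  attention: true
  attention_channels: 1  # 1 = one spatial weight map per level; or d
  literal_subsample_variant: false
detector:
  preset: tiny
  classes: [blotch_red, blotch_blue]
  lr: 0.02
  epochs: 5
  score_thresh: 0.05
  nms_thresh: 0.5
data:
  train_fraction: 0.9
eval:
  iou_thresh: 0.5
  ap_method: all_point
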
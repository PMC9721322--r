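# One panel of a photon-counting detector:
# 2 x 8 readout chips of 97 x 60 pixels (194 x 480), 1-pixel edges.
# Counting mode floors fitted scales at 1/6, so a stuck count v has SNR 6v.
layout:
  asic_height: 97
  asic_width: 60
  n_asic_rows: 2
  n_asic_cols: 8
  edge_width: 1
  module_id: counting_p0
lambda: 8.0
tile_size: 64
window_size: 15
counting_mode: true
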
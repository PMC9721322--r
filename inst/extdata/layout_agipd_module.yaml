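# One module of an AGIPD-like integrating detector:
# 2 x 8 ASICs of 64 x 64 pixels (128 x 512), 1-pixel insensitive edges.
layout:
  asic_height: 64
  asic_width: 64
  n_asic_rows: 2
  n_asic_cols: 8
  edge_width: 1
  module_id: agipd_m0
lambda: 8.0
tile_size: 64
window_size: 15
counting_mode: false
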
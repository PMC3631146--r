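domain:
  length_md: 10.0
  length_og: 10.0
  depth: 1.4
  cell_size: 0.2
appliance:
  bracket_width: 2.4
  bracket_height: 3.0
  bracket_thickness: 1.0
  wire_diameter: 0.3556
  wire_present: no
  bracket_center:
  - 5.0
  - 5.0
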
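# Reduced-scale nine-screw grid (3 x 3) emulating the full implant's screw
# count; mixed screw lengths.
n_screws: 9
centers:
  - [4.5, 4.5]
  - [12.5, 4.5]
  - [20.5, 4.5]
  - [4.5, 12.5]
  - [12.5, 12.5]
  - [20.5, 12.5]
  - [4.5, 20.5]
  - [12.5, 20.5]
  - [20.5, 20.5]
plate: [25, 25, 3]
bone: [11, 2, 0]
screw:
  core_len: [8, 9, 8, 9, 10, 9, 8, 9, 8]
  free_len: 2
  partial_len: 2
bone_field: sampled
field:
  seed: 42
h: 1
order: 1
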
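# Three coupled screws of different lengths in one plate, heterogeneous
# trabecular modulus field; the calibration fixture.
n_screws: 3
plate: [29, 13, 3]
bone: [13, 2, 0]
screw:
  core_len: [8, 10, 12]
  free_len: 3
  partial_len: 2
bone_field: sampled
field:
  seed: 42
h: 1
order: 1
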
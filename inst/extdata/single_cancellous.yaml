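# Single cancellous-type screw through an implant plate into a layered
# bone block; the workhorse verification fixture.
n_screws: 1
plate: [13, 13, 3]
bone: [26, 2, 0]
screw:
  core_len: 22
  free_len: 3
  partial_len: 2
bone_field: homogeneous
h: 1
order: 1
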
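# Single bicortical screw: cortical layers at both block faces and a
# deliberately short free zone (1 mm) that triggers the free-zone
# reliability warning; finer grid so the cut plane fits the free zone.
n_screws: 1
plate: [8, 8, 2]
bone: [8, 1.5, 1.5]
screw:
  core_len: 7
  free_len: 1
  partial_len: 1
  head_h: 1
spec:
  id: cortical
  category: cortical
bone_field: homogeneous
h: 0.5
order: 1
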
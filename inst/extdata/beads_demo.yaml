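# 1:1 mixture of 7 and 10 um polystyrene beads, gated on the
# speed-corrected size product (T1*v) * (T2*vScan).
acquisition:
  noise_sigma: 0.01
  background_amplitude: 0.02
scene:
  classes:
    - label: bead7
      kind: bead
      count: 200
      diameter_um: 7
    - label: bead10
      kind: bead
      count: 200
      diameter_um: 10
gate:
  method: valley
  axes: [sizeProduct]
  target: bead10
  side: above
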
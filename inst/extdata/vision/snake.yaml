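# Colubrid snake trichromat (garter snake, Thamnophis sirtalis: UV, SW and
# LW cones; the retina is strongly LW-dominated). LW Weber fraction 0.05;
# achromatic channel = LW.
name: snake
lambda_max:
  uv: 360
  sw: 482
  lw: 554
eta:
  uv: 1
  sw: 1
  lw: 8
weber_ref: 0.05
achromatic:
  channel: lw
  weber: 0.05
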
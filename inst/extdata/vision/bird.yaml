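# Violet-sensitive raptor tetrachromat (common buzzard, Buteo buteo).
# Abundance ratio 1:2:2:4, LW Weber fraction 0.10; achromatic channel = LW
# (double-cone proxy).
name: bird
lambda_max:
  vs: 405
  sw: 449
  mw: 504
  lw: 567
eta:
  vs: 1
  sw: 2
  mw: 2
  lw: 4
weber_ref: 0.10
achromatic:
  channel: lw
  weber: 0.10
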
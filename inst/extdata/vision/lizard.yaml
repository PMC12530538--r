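# Wall-lizard tetrachromat visual system (Podarcis muralis single-cone
# sensitivities; UV/SW/MW/LW). Abundance ratio 1:1:1:4, LW Weber fraction
# 0.05; achromatic channel = LW (double-cone proxy).
name: lizard
lambda_max:
  uv: 367
  sw: 456
  mw: 497
  lw: 562
eta:
  uv: 1
  sw: 1
  mw: 1
  lw: 4
weber_ref: 0.05
achromatic:
  channel: lw
  weber: 0.05
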
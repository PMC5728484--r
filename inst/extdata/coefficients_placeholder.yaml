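# PLACEHOLDER coefficient configuration for the habitat suitability
# equation. The intercept (3.07) is the published value for the corrected
# pheasant-habitat model; the ten slopes below are synthetic placeholders
# chosen only for sign plausibility (grassland and wetland positive, trees
# negative, hump-shaped crop responses). Replace the slopes with fitted
# values before drawing conclusions about any real landscape.
intercept: 3.07
slopes:
  rangeland: 1.5
  crp: 2.0
  row_crop: 4.0
  row_crop2: -6.0
  row_crop3: 1.5
  small_grain: 1.0
  small_grain2: -1.0
  small_grain3: 0.2
  trees: -4.0
  wetland: 2.0
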
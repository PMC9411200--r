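# Example protocol config: 12 entrained days, 11 days of constant
# darkness, then a restricted-feeding block with the standard adaptation
# ramp (ZT8-16, ZT8-14, then ZT8-12), 2 ad-lib days and a 48-h
# deprivation retention probe.
light:
  - {type: LD, on: "06:00", off: "18:00", days: 12}
  - {type: DD, days: 11}
feeding:
  training_days: 12
  start_day: 0
  adlib_days: 2
  deprivation_days: 2
  expected_food_zt: 8
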
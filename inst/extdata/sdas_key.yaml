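items:
- SDAS_R_01
- SDAS_02
- SDAS_03
- SDAS_04
- SDAS_05
- SDAS_06
- SDAS_07
- SDAS_R_08
- SDAS_09
- SDAS_R_10
- SDAS_11
- SDAS_12
- SDAS_13
- SDAS_14
- SDAS_15
- SDAS_16
- SDAS_17
- SDAS_18
- SDAS_19
- SDAS_20
- SDAS_21
- SDAS_22
- SDAS_23
- SDAS_R_24
- SDAS_25
- SDAS_26
- SDAS_27
- SDAS_28
- SDAS_29
- SDAS_30
- SDAS_R_31
- SDAS_32
- SDAS_33
- SDAS_34
- SDAS_R_35
- SDAS_36
- SDAS_37
factors:
  economy:
  - SDAS_R_01
  - SDAS_02
  - SDAS_03
  - SDAS_04
  - SDAS_05
  - SDAS_06
  - SDAS_07
  - SDAS_R_08
  - SDAS_09
  - SDAS_R_10
  - SDAS_11
  - SDAS_12
  - SDAS_13
  society:
  - SDAS_14
  - SDAS_15
  - SDAS_16
  - SDAS_17
  - SDAS_18
  - SDAS_19
  - SDAS_20
  - SDAS_21
  - SDAS_22
  environment:
  - SDAS_23
  - SDAS_R_24
  - SDAS_25
  - SDAS_27
  - SDAS_28
  - SDAS_29
  - SDAS_30
  - SDAS_R_31
  - SDAS_32
  - SDAS_33
  - SDAS_34
  - SDAS_R_35
  - SDAS_36
  - SDAS_37
reverse_items:
- SDAS_R_01
- SDAS_R_08
- SDAS_R_10
- SDAS_R_24
- SDAS_R_31
- SDAS_R_35
scale:
  min: 1
  max: 5
instructed_item:
  id: SDAS_26
  required_category: 3
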
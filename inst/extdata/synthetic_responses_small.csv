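respondent_id,SDAS_R_01,SDAS_02,SDAS_03,SDAS_04,SDAS_05,SDAS_06,SDAS_07,SDAS_R_08,SDAS_09,SDAS_R_10,SDAS_11,SDAS_12,SDAS_13,SDAS_14,SDAS_15,SDAS_16,SDAS_17,SDAS_18,SDAS_19,SDAS_20,SDAS_21,SDAS_22,SDAS_23,SDAS_R_24,SDAS_25,SDAS_26,SDAS_27,SDAS_28,SDAS_29,SDAS_30,SDAS_R_31,SDAS_32,SDAS_33,SDAS_34,SDAS_R_35,SDAS_36,SDAS_37
R00001,1,4,3,5,4,4,5,2,4,1,5,5,5,5,4,4,4,3,3,4,4,5,5,2,5,3,5,5,5,4,1,5,5,5,2,5,5
R00002,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2,2
R00003,2,4,2,4,5,4,5,2,3,1,4,5,3,4,5,5,4,3,4,5,3,5,5,2,5,3,5,4,4,5,1,4,5,5,2,5,5
R00004,4,3,5,5,4,5,4,2,5,3,4,3,5,5,3,5,4,3,3,4,4,4,5,2,3,3,4,3,5,2,1,4,4,4,5,3,3
R00005,3,5,3,5,5,3,5,1,4,2,4,5,4,2,4,3,4,4,3,4,4,2,3,5,5,3,4,3,2,3,2,3,2,2,3,3,2
R00006,2,5,2,3,4,5,3,1,4,1,5,4,5,5,4,4,3,5,3,4,4,4,4,3,3,3,3,4,4,4,2,4,5,3,3,3,5
R00007,2,5,4,5,5,4,5,3,5,2,5,5,5,3,4,4,4,5,4,5,2,3,4,2,5,3,4,3,4,5,3,5,5,5,2,4,4
R00008,2,3,3,3,4,3,3,3,4,2,5,4,4,3,4,4,5,4,4,5,5,5,4,4,3,3,1,1,4,1,4,4,3,3,3,2,4
R00009,4,4,5,5,3,5,3,2,4,5,3,4,5,5,3,3,5,4,3,4,5,5,4,3,4,3,3,5,5,4,2,4,5,5,4,5,5
R00010,3,2,2,1,3,3,4,2,1,2,2,1,1,1,4,1,3,3,2,1,3,3,3,1,3,3,3,4,3,3,3,4,3,4,1,2,4
R00011,1,3,4,2,4,4,3,2,3,3,4,3,5,3,4,4,4,3,4,1,3,4,3,5,4,3,1,4,2,4,1,3,4,3,1,3,3
R00012,3,5,2,3,3,4,3,3,4,1,5,4,4,4,2,4,4,3,5,4,4,1,4,3,4,3,5,3,5,3,2,3,4,4,3,5,4
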
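name,z,mass_da,ccs_a2,td_ms
synthetic_cal_01,7,8560,1128.1158,4
synthetic_cal_02,8,12360,1613.3348,6
synthetic_cal_03,9,16950,2127.3706,8
synthetic_cal_04,7,8560,1875.0094,10
synthetic_cal_05,8,12360,2368.112,12
synthetic_cal_06,9,16950,2899.3592,14
synthetic_cal_07,7,8560,2430.5975,16
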
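participant,f_max_mmhg,f_med_mmhg,f_min_mmhg,skin_temp_c,room_temp_c
S1,55.0,21.3,15.6,34.1,21.8
S2,40.9,15.3,7.7,31.1,21.2
S3,34.0,14.0,8.3,32.2,23.3
S4,51.6,29.8,21.0,32.3,22.5
S5,39.7,21.3,12.3,34.1,23.7
S6,40.6,15.7,10.2,28.9,23.5
S7,51.1,37.6,9.3,32.1,22.6
S8,35.9,16.8,3.2,36.2,24.3
S9,36.0,16.3,5.6,31.9,24.6
S10,35.7,32.6,24.5,31.1,22.5
S11,42.2,38.0,13.8,32.4,22.5
S12,47.1,27.5,17.3,35.3,22.7
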
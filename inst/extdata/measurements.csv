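sample_id,temperature_C,epsilon_r,run
I,30,68,1
I,55,370,1
P1,30,27,1
P1,55,31,1
P2,30,24,1
P3,30,22,1
IZnO_S,30,40,1
IZnO_S,55,167,1
IZnO_T,30,95,1
IZnO_T,55,351,1
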
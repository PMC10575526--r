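id,length_um,diameter_um,depth_um
feeder,95,9.6,160
cap_a,62,4.8,150
cap_b,58,4.1,155
cap_c,64,4.4,148
cap_d,71,3.9,198
collector,80,6.9,201
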
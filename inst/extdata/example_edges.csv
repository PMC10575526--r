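junction_id,kind,parent_id,daughter1_id,daughter2_id
J1,BIFURCATION,feeder,cap_a,cap_b
J2,BIFURCATION,cap_a,cap_c,cap_d
J3,CONFLUENCE,collector,cap_c,cap_d
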
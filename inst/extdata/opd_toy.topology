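# emip topology v1
name opd_toy
role monomer
net_charge 0
sites 3
label element sigma epsilon charge x y z
R1 C 3.55 0.07 -0.3 0 0 0
D1 N 2.8 1.5 0.15 1.2 0.7 0
D2 N 2.8 1.5 0.15 1.2 -0.7 0
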
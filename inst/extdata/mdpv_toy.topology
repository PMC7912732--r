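# emip topology v1
name mdpv_toy
role template
net_charge 1
sites 5
label element sigma epsilon charge x y z
C1 C 4.5 0.3 0.8 0 0 0
N1 N 3.3 0.17 0.8 1.3 0 0
O1 O 2.6 1.5 -0.2 -1.5 1 0
O2 O 2.6 1.5 -0.2 -1.5 -1 0
O3 O 2.65 1.7 -0.2 0.3 1.8 0.6
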
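# emip topology v1
name water_toy
role solvent
net_charge 0
sites 1
label element sigma epsilon charge x y z
OW O 3.16 0.155 0 0 0 0
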
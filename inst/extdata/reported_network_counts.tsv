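metric	value
nodes_fungi	470
nodes_bacteria	93
nodes_archaea	147
nodes_total	710
edges_total	10812
connectivity_reported	15.2
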
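variant_label	call	figure
Δ284-288	retained	5-nt scan
Δ287-291	abrogated	5-nt scan
Δ290-294	abrogated	5-nt scan
Δ293-297	abrogated	5-nt scan
Δ296-300	retained	5-nt scan
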
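variant_label	call	figure
Δ261-270	retained	10-nt scan
Δ266-275	retained	10-nt scan
Δ271-280	retained	10-nt scan
Δ276-285	retained	10-nt scan
Δ281-290	abrogated	10-nt scan
Δ286-295	abrogated	10-nt scan
Δ291-300	abrogated	10-nt scan
Δ296-305	partial	10-nt scan
Δ301-310	retained	10-nt scan
Δ306-315	retained	10-nt scan
Δ311-320	retained	10-nt scan
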
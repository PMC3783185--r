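variant_label	call	figure
Δ192-211	retained	20-nt scan
Δ202-221	retained	20-nt scan
Δ212-231	retained	20-nt scan
Δ222-241	retained	20-nt scan
Δ232-251	retained	20-nt scan
Δ242-261	retained	20-nt scan
Δ252-271	retained	20-nt scan
Δ262-281	partial	20-nt scan
Δ271-290	abrogated	20-nt scan
Δ281-300	abrogated	20-nt scan
Δ291-310	abrogated	20-nt scan
Δ301-320	retained	20-nt scan
Δ311-330	retained	20-nt scan
Δ325-344	retained	20-nt scan
Δ333-352	retained	20-nt scan
Δ341-360	retained	20-nt scan
Δ349-368	retained	20-nt scan
Δ357-376	retained	20-nt scan
Δ365-384	retained	20-nt scan
Δ373-392	retained	20-nt scan
Δ381-400	retained	20-nt scan
Δ386-405	retained	20-nt scan
Δ391-410	retained	20-nt scan
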
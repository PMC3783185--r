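variant_label	aso	observed	clear	figure
Δ192-211	L14	inhibitory	TRUE	20-nt scan
Δ202-221	L14	inhibitory	TRUE	20-nt scan
Δ212-231	L14	inhibitory	TRUE	20-nt scan
Δ222-241	L14	inhibitory	TRUE	20-nt scan
Δ232-251	L14	inhibitory	TRUE	20-nt scan
Δ242-261	L14	inhibitory	TRUE	20-nt scan
Δ252-271	L14	inhibitory	TRUE	20-nt scan
Δ262-281	L14	NA	FALSE	20-nt scan
Δ271-290	L14	stimulatory	TRUE	20-nt scan
Δ281-300	L14	stimulatory	TRUE	20-nt scan
Δ291-310	L14	stimulatory	TRUE	20-nt scan
Δ301-320	L14	inhibitory	TRUE	20-nt scan
Δ311-330	L14	inhibitory	TRUE	20-nt scan
Δ325-344	L14	inhibitory	TRUE	20-nt scan
Δ333-352	L14	inhibitory	TRUE	20-nt scan
Δ341-360	L14	inhibitory	TRUE	20-nt scan
Δ349-368	L14	inhibitory	TRUE	20-nt scan
Δ357-376	L14	inhibitory	TRUE	20-nt scan
Δ365-384	L14	inhibitory	TRUE	20-nt scan
Δ373-392	L14	inhibitory	TRUE	20-nt scan
Δ381-400	L14	inhibitory	TRUE	20-nt scan
Δ386-405	L14	inhibitory	TRUE	20-nt scan
Δ391-410	L14	inhibitory	TRUE	20-nt scan
Δ261-270	L14	inhibitory	TRUE	10-nt scan
Δ266-275	L14	inhibitory	TRUE	10-nt scan
Δ271-280	L14	inhibitory	TRUE	10-nt scan
Δ276-285	L14	inhibitory	TRUE	10-nt scan
Δ281-290	L14	stimulatory	TRUE	10-nt scan
Δ286-295	L14	stimulatory	TRUE	10-nt scan
Δ291-300	L14	stimulatory	TRUE	10-nt scan
Δ296-305	L14	NA	FALSE	10-nt scan
Δ301-310	L14	inhibitory	TRUE	10-nt scan
Δ306-315	L14	inhibitory	TRUE	10-nt scan
Δ311-320	L14	inhibitory	TRUE	10-nt scan
Δ284-288	L14	inhibitory	TRUE	5-nt scan
Δ287-291	L14	stimulatory	TRUE	5-nt scan
Δ290-294	L14	stimulatory	TRUE	5-nt scan
Δ293-297	L14	stimulatory	TRUE	5-nt scan
Δ296-300	L14	inhibitory	TRUE	5-nt scan
288U	L14	inhibitory	TRUE	point scan
289G	L14	inhibitory	TRUE	point scan
290C	L14	stimulatory	TRUE	point scan
291G	L14	stimulatory	TRUE	point scan
292G	L14	stimulatory	TRUE	point scan
293C	L14	stimulatory	TRUE	point scan
294C	L14	stimulatory	TRUE	point scan
295G	L14	stimulatory	TRUE	point scan
296G	L14	inhibitory	TRUE	point scan
297G	L14	inhibitory	TRUE	point scan
WT	L14	inhibitory	TRUE	WT
Δ93-281	L14	inhibitory	TRUE	large deletions
Δ330-412	L14	inhibitory	TRUE	large deletions
Δ290-295	L14	stimulatory	TRUE	motif swap
Δ282-287	L14	inhibitory	TRUE	motif swap
8C	L14	stimulatory	TRUE	compensatory series
10G	L14	stimulatory	TRUE	compensatory series
290C	L14	stimulatory	TRUE	compensatory series
292G	L14	stimulatory	TRUE	compensatory series
8C/292G	L14	inhibitory	TRUE	compensatory series
10G/290C	L14	inhibitory	FALSE	compensatory series
WT	F14	stimulatory	TRUE	F14 response
Δ192-211	F14	stimulatory	TRUE	F14 response
Δ202-221	F14	stimulatory	TRUE	F14 response
Δ212-231	F14	stimulatory	TRUE	F14 response
Δ222-241	F14	stimulatory	TRUE	F14 response
Δ232-251	F14	stimulatory	TRUE	F14 response
Δ242-261	F14	stimulatory	TRUE	F14 response
Δ252-271	F14	stimulatory	TRUE	F14 response
Δ262-281	F14	stimulatory	TRUE	F14 response
Δ271-290	F14	stimulatory	TRUE	F14 response
Δ281-300	F14	stimulatory	TRUE	F14 response
Δ291-310	F14	stimulatory	TRUE	F14 response
Δ301-320	F14	stimulatory	TRUE	F14 response
Δ311-330	F14	stimulatory	TRUE	F14 response
Δ325-344	F14	stimulatory	TRUE	F14 response
Δ333-352	F14	stimulatory	TRUE	F14 response
Δ341-360	F14	stimulatory	TRUE	F14 response
Δ349-368	F14	stimulatory	TRUE	F14 response
Δ357-376	F14	stimulatory	TRUE	F14 response
Δ365-384	F14	stimulatory	TRUE	F14 response
Δ373-392	F14	stimulatory	TRUE	F14 response
Δ381-400	F14	stimulatory	TRUE	F14 response
Δ386-405	F14	stimulatory	TRUE	F14 response
Δ391-410	F14	stimulatory	TRUE	F14 response
Δ261-270	F14	stimulatory	TRUE	F14 response
Δ266-275	F14	stimulatory	TRUE	F14 response
Δ271-280	F14	stimulatory	TRUE	F14 response
Δ276-285	F14	stimulatory	TRUE	F14 response
Δ281-290	F14	stimulatory	TRUE	F14 response
Δ286-295	F14	stimulatory	TRUE	F14 response
Δ291-300	F14	stimulatory	TRUE	F14 response
Δ296-305	F14	stimulatory	TRUE	F14 response
Δ301-310	F14	stimulatory	TRUE	F14 response
Δ306-315	F14	stimulatory	TRUE	F14 response
Δ311-320	F14	stimulatory	TRUE	F14 response
288U/289G	F14	stimulatory	TRUE	F14 response
286G/288U/289G/298A	F14	stimulatory	TRUE	F14 response
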
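variant_label	call	figure
288U	retained	point scan
289G	retained	point scan
290C	abrogated	point scan
291G	abrogated	point scan
292G	abrogated	point scan
293C	abrogated	point scan
294C	abrogated	point scan
295G	abrogated	point scan
296G	retained	point scan
297G	retained	point scan
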
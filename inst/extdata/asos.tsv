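name	start	end
F14	1	14
L14	11	24
Anti-N1	10	29
ASO 276-290	276	290
ASO 283-297	283	297
ASO-M	275	297
ASO-D	-9	14
ASO-N2	275	297
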
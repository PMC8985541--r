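chrom	pos	strand	label
chrAmp	420	+	A
chrAmp	425	+	B
chrAmp	432	+	C
chrAmp	437	+	D
chrAmp	444	+	E
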
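string_id	uniprot_ac
9606.ENSP00000252338	P07225
9606.ENSP00000269305	P04637
4932.YEL013W	P39968
3702.AT1G58030	P52569
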
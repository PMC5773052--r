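uniprot_ac	go_id
P07225	GO:0005886
P52569	GO:0009705
P39968	GO:0005773
P32915	GO:0005783
P04637	GO:0005634
Q9SRV5	GO:0009707
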
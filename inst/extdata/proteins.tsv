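name	norm_id	taxid
CAT2	P52569	3702
OsACBP2	Q9STP8	39947
PROS1	P07225	9606
Protein S	P07225	9606
TP53	P04637	9606
NEMO	Q9Y6K9	9606
CX43	P17302	9606
FIP3	O75154	9606
VAC8	P39968	4932
SEC61	P32915	4932
PEX5	P35056	4932
SNX1	Q13596	9606
TOC33	Q9SRV5	3702
GFP	P42212	6100
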
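name
GFP
green fluorescent protein
RFP
red fluorescent protein
YFP
yellow fluorescent protein
CFP
cyan fluorescent protein
mCherry
luciferase
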
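name	norm_id
tonoplast	GO:0009705
plasma membrane	GO:0005886
cell membrane	GO:0005886
lateral plasma membrane	GO:0016328
nucleus	GO:0005634
nucleolus	GO:0005730
mitochondrion	GO:0005739
mitochondrial matrix	GO:0005759
vacuole	GO:0005773
vacuolar membrane	GO:0005774
cytosol	GO:0005829
endoplasmic reticulum	GO:0005783
Golgi	GO:0005794
Golgi apparatus	GO:0005794
extracellular region	GO:0005576
proteasome complex	GO:0000502
peroxisome	GO:0005777
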
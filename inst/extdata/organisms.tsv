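name	norm_id
human	9606
Homo sapiens	9606
yeast	4932
Saccharomyces cerevisiae	4932
Arabidopsis	3702
Arabidopsis thaliana	3702
thale cress	3702
rice	39947
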
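name	entrez_id	name_type
BRCA1	672	symbol
breast cancer 1	672	full_name
TP53	7157	symbol
tumor protein p53	7157	full_name
ESR1	2099	symbol
estrogen receptor alpha	2099	full_name
PTEN	5728	symbol
CAT	847	symbol
catalase	847	full_name
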
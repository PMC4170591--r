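pattern_id	level	regex
nt_hgvs_c	nucleotide	\bc\.(?<pos>-?\d+)\s*(?<wild>%NT%)\s*(?:>|-->|->|→)\s*(?<mut>%NT%)(?![A-Za-z0-9])
nt_pos_sub	nucleotide	\b(?<pos>\d+)\s*(?<wild>%NT%)\s*(?:>|-->|->|→)\s*(?<mut>%NT%)(?![A-Za-z0-9])
prot_p3	protein	\bp\.(?<wild>%AA3%)(?<pos>\d+)(?<mut>%AA3%)(?![A-Za-z0-9])
prot_p1	protein	\bp\.(?<wild>%AA1%)(?<pos>\d+)(?<mut>%AA1%)(?![A-Za-z0-9])
prot_aa3	protein	\b(?<wild>%AA3%)[ \t-]*(?<pos>\d+)[ \t-]*(?<mut>%AA3%)\b
prot_aa1	protein	\b(?<wild>%AA1%)(?<pos>\d+)(?<mut>%AA1%)\b
nt_to_at	nucleotide	\b(?<wild>%NT%)\s+to\s+(?<mut>%NT%)(?:\s+(?:substitution|transition|transversion|change|mutation))?\s+at\s+(?:position|nucleotide|base|nt)\s+(?<pos>\d+)\b
aa3_to_at	protein	\b(?<wild>%AA3%)\s+to\s+(?<mut>%AA3%)(?:\s+(?:substitution|change|mutation))?\s+at\s+(?:position|codon|residue)\s+(?<pos>\d+)\b
aa3_to_pair	protein	\b(?<wild>%AA3%)\s+to\s+(?<mut>%AA3%)\b
aa3_for_pair	protein	\bsubstitution\s+of\s+(?<mut>%AA3%)\s+for\s+(?<wild>%AA3%)\b
aa3_arrow	protein	\b(?<wild>%AA3%)\s*(?:→|-->|->)\s*(?<mut>%AA3%)\b
nt_arrow	nucleotide	\b(?<wild>%NT%)\s*(?:→|-->|->)\s*(?<mut>%NT%)(?![A-Za-z0-9])
nt_to_pair	nucleotide	\b(?<wild>%NT%)\s+to\s+(?<mut>%NT%)\b
dbsnp	dbsnp	\brs\d+\b
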
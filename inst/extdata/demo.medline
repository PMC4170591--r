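PMID- 9001001
TI  - A BRCA1 missense variant in early-onset breast cancer.
AB  - We screened 40 families and identified the c.181T>G variant in BRCA1 (breast cancer 1). Carriers of the resulting Cys 61 Gly substitution showed loss of RING function. The T47D cells served as controls.

PMID- 9001002
TI  - TP53 alterations in sporadic tumors.
AB  - Tumors frequently harbored the R175H substitution in TP53 (tumor protein p53). An additional change of G to A at position 524 was noted in two cases. Expression of catalase (CAT) was unchanged across genotypes.

PMID- 9001003
TI  - Hormone receptor signalling and resistance.
AB  - Antagonists selective for estrogen receptor alpha (ESR1) reversed the effect of the Lys303Arg substitution. Reporter assays used chloramphenicol acetyltransferase (CAT) constructs.

PMID- 9001004
TI  - A common TP53 polymorphism.
AB  - We found a substitution of Pro for Ser at codon 72 of TP53 (tumor protein p53). The dbSNP entry rs35490896 was also genotyped in the same cohort.

PMID- 9001005
TI  - Coding and noncoding PTEN variation.
AB  - A promoter variant c.-34C>T was identified in PTEN. In intron 4, a change of A to G at position 1200 was also seen; the PTEN H123Y substitution was the only coding change.
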
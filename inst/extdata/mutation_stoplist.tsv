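stop_id	regex
cell_line_known	\b(?:T47D|MCF7|MCF10A|HEK293T?|K562|A549|PC12|U2OS|HCT116|SKBR3|COS7|NIH3T3|HL60|U937|SW480)\b
cell_line_ctx	\b[A-Z]{1,6}-?\d+[A-Z]?\d*\s+cell(?:s|\s+line)?\b
chromosome_band	\b(?:[1-9]|1[0-9]|2[0-2]|X|Y)[pq]\d+(?:\.\d+)?\b
units	\b\d+\s*(?:bp|kb|Mb|kDa|Da|nm|mM|uM|mg|ml|min|h)\b
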
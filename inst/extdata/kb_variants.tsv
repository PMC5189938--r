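gene	protein_change	impact_score	seen_in_endometrial	seen_in_other_cancers
TP53	C176F	high	FALSE	TRUE
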
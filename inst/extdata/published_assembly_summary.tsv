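# Published general features of the ATCC 10970 genome assembly (reported
# summary values; inputs for desk-check arithmetic, not computed here).
# replicon	length_bp	circular	gc_percent	cds
chromosome	9365899	No	72.0	8085
plasmid	292604	No	69.6	282
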
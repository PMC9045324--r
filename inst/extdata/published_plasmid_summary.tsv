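# Published general features of the three sequenced giant linear plasmids
# (reported summary values; the R6 row describes the collapsed 189,563-bp
# contig, with the proposed full-length values in the *_full columns).
# strain	length_bp	gc_percent	cds	median_cds_bp	transposases	regulators	hypotheticals
WT5260	292604	69.6	282	621	21	18	148
M4018	299299	69.5	291	618	23	18	152
R6	189563	69.8	202	564	14	11	117
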
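# Published biosynthetic gene cluster interval on the chromosome
# (1-based inclusive coordinates as printed in the genome report).
# name	start_bp	end_bp
rms	90930	97183
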
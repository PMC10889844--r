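gene	position	column	printed	corrected	note
LOC132634709	1439	reference	Gly	Lys	printed codons AAA/AAG encode Lys, not Gly
LOC132634709	1761	reference	Tyr	Thr	printed reference codon ACG encodes Thr, not Tyr
LOC132634709	1761	Lb6w	Tyr	Thr	printed reference codon ACG encodes Thr, not Tyr
LOC132634709	1761	Lb7w	Tyr	Thr	printed reference codon ACG encodes Thr, not Tyr
LOC132634709	1761	Lb8w	Tyr	Thr	printed reference codon ACG encodes Thr, not Tyr
LOC132607278	824	reference	Pro	Ser	printed reference codon TCT encodes Ser, not Pro
LOC132609965	1285	Lb7w	h775	h75	heterozygous fraction above 100% is impossible; read as h75
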
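# Repetitive-element tallies over 57,891,795 bp of non-ambiguous transcriptome
# sequence. length_bp_raw preserves the printed figure (including the
# misplaced-comma "31,8339"); length_bp is the interpreted value consistent
# with the printed percentage column.
class	n_elements	length_bp_raw	length_bp	percent
Retroelements	728	76,814	76814	0.13
Penelope	3	165	165	0.00
LINEs	359	32, 845	32845	0.06
LTR elements	369	43, 969	43969	0.08
DNA transposon	124	13,313	13313	0.02
Unclassified	11	554	554	0.00
Total interspersed repeats	NA	90,681	90681	0.16
Satellites	6	675	675	0.00
Simple repeats	8332	31,8339	318339	0.55
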
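# In-vivo reference sign matrix (5 parameters x 3 mutants), entries -1/0/+1:
# direction of each significant mutant-vs-wild-type change of the GAL1
# readouts.  PARTLY SYNTHETIC: nine cells follow from textual statements
# about the wet-lab results; the six cells marked (f) below are a
# transcription by the package authors from the figure panel, chosen from
# domain knowledge (deadenylase/exonuclease nulls lengthen half-life;
# genome-wide RNAPII ChIP occupancy is reduced in the xrn1 null; mRNA
# accumulates when the major 5'->3' exonuclease is absent), fixed once
# before model calibration.
#
# provenance: total_mrna      text  text  figure_synthetic(f, sign only)
#             half_life       (f)   (f)   text
#             total_rnapii    (f)   (f)   (f)
#             active_rnapii   text  text  text
#             speed           text  text  text
parameter	dst1d	ccr4d	xrn1d
total_mrna	0	0	1
half_life	1	1	1
total_rnapii	0	0	-1
active_rnapii	-1	-1	-1
speed	0	0	-1
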
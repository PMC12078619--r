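# Apparent specific volumes (cm^3/g) of gabapentin in aqueous betaine-based
# media at 298 K, as printed. Note: in the source, the DES 0.01 column's ASV
# cells are cyclically misaligned against their own molality rows (they are a
# rotation of the values implied by the printed apparent molar volumes).
system,solvent_molality_nominal,m,asv,provenance
betaine,0.01,0.0010,0.810,Tab4 betaine 0.01
betaine,0.01,0.0049,0.822,Tab4 betaine 0.01
betaine,0.01,0.0100,0.818,Tab4 betaine 0.01
betaine,0.01,0.0201,0.823,Tab4 betaine 0.01
betaine,0.01,0.0293,0.825,Tab4 betaine 0.01
betaine,0.03,0.0010,0.826,Tab4 betaine 0.03
betaine,0.03,0.0049,0.834,Tab4 betaine 0.03
betaine,0.03,0.0099,0.830,Tab4 betaine 0.03
betaine,0.03,0.0204,0.831,Tab4 betaine 0.03
betaine,0.03,0.0298,0.832,Tab4 betaine 0.03
betaine,0.05,0.0010,0.825,Tab4 betaine 0.05
betaine,0.05,0.0050,0.836,Tab4 betaine 0.05
betaine,0.05,0.0097,0.838,Tab4 betaine 0.05
betaine,0.05,0.0200,0.834,Tab4 betaine 0.05
betaine,0.05,0.0294,0.835,Tab4 betaine 0.05
des,0.01,0.0019,0.834,Tab4 DES 0.01 (misaligned column)
des,0.01,0.0050,0.833,Tab4 DES 0.01 (misaligned column)
des,0.01,0.0100,0.836,Tab4 DES 0.01 (misaligned column)
des,0.01,0.0200,0.838,Tab4 DES 0.01 (misaligned column)
des,0.01,0.0295,0.823,Tab4 DES 0.01 (misaligned column)
des,0.03,0.0010,0.833,Tab4 DES 0.03
des,0.03,0.0050,0.831,Tab4 DES 0.03
des,0.03,0.0099,0.834,Tab4 DES 0.03
des,0.03,0.0200,0.836,Tab4 DES 0.03
des,0.03,0.0296,0.839,Tab4 DES 0.03
des,0.05,0.0010,0.831,Tab4 DES 0.05
des,0.05,0.0050,0.831,Tab4 DES 0.05
des,0.05,0.0099,0.838,Tab4 DES 0.05
des,0.05,0.0193,0.838,Tab4 DES 0.05
des,0.05,0.0298,0.840,Tab4 DES 0.05
il,0.01,0.0010,0.819,Tab4 IL 0.01
il,0.01,0.0050,0.825,Tab4 IL 0.01
il,0.01,0.0099,0.824,Tab4 IL 0.01
il,0.01,0.0198,0.826,Tab4 IL 0.01
il,0.01,0.0301,0.829,Tab4 IL 0.01
il,0.03,0.0010,0.819,Tab4 IL 0.03
il,0.03,0.0049,0.834,Tab4 IL 0.03
il,0.03,0.0099,0.835,Tab4 IL 0.03
il,0.03,0.0203,0.836,Tab4 IL 0.03
il,0.03,0.0299,0.837,Tab4 IL 0.03
il,0.05,0.0010,0.822,Tab4 IL 0.05
il,0.05,0.0049,0.832,Tab4 IL 0.05
il,0.05,0.0100,0.841,Tab4 IL 0.05
il,0.05,0.0199,0.838,Tab4 IL 0.05
il,0.05,0.0289,0.842,Tab4 IL 0.05
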
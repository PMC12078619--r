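# Viscosities (mPa s) of gabapentin in aqueous betaine-based media at 298 K.
# m = 0 rows are the pure-solvent reference (eta0).
# The IL block's solvent row is garbled in the source (printed tokens
# "0.00 / 0.0000 / 0.0000 / 0.8988" cannot be assigned unambiguously to the
# three series), so eta0 is recorded as missing for all three IL series and
# must be supplied to any fit.
system,solvent_molality_nominal,solvent_molality,m,value,provenance
betaine,0.01,0.0101,0.0000,0.881,Tab6 betaine 0.01
betaine,0.01,0.0101,0.0010,0.883,Tab6 betaine 0.01
betaine,0.01,0.0101,0.0049,0.885,Tab6 betaine 0.01
betaine,0.01,0.0101,0.0100,0.887,Tab6 betaine 0.01
betaine,0.01,0.0101,0.0201,0.893,Tab6 betaine 0.01
betaine,0.01,0.0101,0.0293,0.896,Tab6 betaine 0.01
betaine,0.03,0.0297,0.0000,0.885,Tab6 betaine 0.03
betaine,0.03,0.0297,0.0010,0.890,Tab6 betaine 0.03
betaine,0.03,0.0297,0.0049,0.895,Tab6 betaine 0.03
betaine,0.03,0.0297,0.0099,0.897,Tab6 betaine 0.03
betaine,0.03,0.0297,0.0204,0.897,Tab6 betaine 0.03
betaine,0.03,0.0297,0.0298,0.904,Tab6 betaine 0.03
betaine,0.05,0.0498,0.0000,0.892,Tab6 betaine 0.05
betaine,0.05,0.0498,0.0009,0.897,Tab6 betaine 0.05
betaine,0.05,0.0498,0.0049,0.901,Tab6 betaine 0.05
betaine,0.05,0.0498,0.0097,0.903,Tab6 betaine 0.05
betaine,0.05,0.0498,0.0200,0.904,Tab6 betaine 0.05
betaine,0.05,0.0498,0.0294,0.906,Tab6 betaine 0.05
des,0.01,0.0099,0.0000,0.883,Tab6 DES 0.01
des,0.01,0.0099,0.0019,0.887,Tab6 DES 0.01
des,0.01,0.0099,0.0050,0.892,Tab6 DES 0.01
des,0.01,0.0099,0.0100,0.898,Tab6 DES 0.01
des,0.01,0.0099,0.0200,0.904,Tab6 DES 0.01
des,0.01,0.0099,0.0295,0.908,Tab6 DES 0.01
des,0.03,0.0298,0.0000,0.889,Tab6 DES 0.03
des,0.03,0.0298,0.0010,0.894,Tab6 DES 0.03
des,0.03,0.0298,0.0050,0.898,Tab6 DES 0.03
des,0.03,0.0298,0.0099,0.901,Tab6 DES 0.03
des,0.03,0.0298,0.0200,0.906,Tab6 DES 0.03
des,0.03,0.0298,0.0296,0.91,Tab6 DES 0.03
des,0.05,0.0504,0.0000,0.897,Tab6 DES 0.05
des,0.05,0.0504,0.0010,0.905,Tab6 DES 0.05
des,0.05,0.0504,0.0050,0.907,Tab6 DES 0.05
des,0.05,0.0504,0.0099,0.909,Tab6 DES 0.05
des,0.05,0.0504,0.0193,0.911,Tab6 DES 0.05
des,0.05,0.0504,0.0298,0.915,Tab6 DES 0.05
il,0.01,0.0102,0.0000,,Tab6 IL 0.01 (solvent row garbled in source)
il,0.01,0.0102,0.0010,0.888,Tab6 IL 0.01
il,0.01,0.0102,0.0050,0.89,Tab6 IL 0.01
il,0.01,0.0102,0.0099,0.894,Tab6 IL 0.01
il,0.01,0.0102,0.0198,0.9,Tab6 IL 0.01
il,0.01,0.0102,0.0301,0.91,Tab6 IL 0.01
il,0.03,0.0301,0.0000,,Tab6 IL 0.03 (solvent row garbled in source)
il,0.03,0.0301,0.0010,0.897,Tab6 IL 0.03
il,0.03,0.0301,0.0049,0.901,Tab6 IL 0.03
il,0.03,0.0301,0.0099,0.904,Tab6 IL 0.03
il,0.03,0.0301,0.0203,0.91,Tab6 IL 0.03
il,0.03,0.0301,0.0299,0.915,Tab6 IL 0.03
il,0.05,0.0503,0.0000,,Tab6 IL 0.05 (solvent row garbled in source)
il,0.05,0.0503,0.0010,0.921,Tab6 IL 0.05
il,0.05,0.0503,0.0049,0.925,Tab6 IL 0.05
il,0.05,0.0503,0.0100,0.929,Tab6 IL 0.05
il,0.05,0.0503,0.0199,0.937,Tab6 IL 0.05
il,0.05,0.0503,0.0289,0.927,Tab6 IL 0.05
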
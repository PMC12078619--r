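# Densities (g/cm^3) and printed apparent molar volumes (cm^3/mol) of
# gabapentin in aqueous betaine-based media at 298 K.
# m = 0 rows are the pure-solvent reference (rho0); vphi_printed is empty there.
# solvent_molality is the printed additive molality where the source prints
# one for the block; otherwise the nominal level.
system,solvent_molality_nominal,solvent_molality,m,value,vphi_printed,provenance
betaine,0.01,0.0102,0.0000,0.99819,,Tab2 betaine 0.01
betaine,0.01,0.0102,0.0010,0.99822,138.747,Tab2 betaine 0.01
betaine,0.01,0.0102,0.0049,0.99834,140.697,Tab2 betaine 0.01
betaine,0.01,0.0102,0.0100,0.99850,140.154,Tab2 betaine 0.01
betaine,0.01,0.0102,0.0201,0.99880,140.851,Tab2 betaine 0.01
betaine,0.01,0.0102,0.0293,0.99907,141.21,Tab2 betaine 0.01
betaine,0.03,0.0306,0.0000,0.99870,,Tab2 betaine 0.03
betaine,0.03,0.0306,0.0010,0.99870,141.474,Tab2 betaine 0.03
betaine,0.03,0.0306,0.0049,0.99881,142.774,Tab2 betaine 0.03
betaine,0.03,0.0306,0.0099,0.99896,142.115,Tab2 betaine 0.03
betaine,0.03,0.0306,0.0204,0.99926,142.372,Tab2 betaine 0.03
betaine,0.03,0.0306,0.0298,0.99953,142.427,Tab2 betaine 0.03
betaine,0.05,0.0498,0.0000,0.99900,,Tab2 betaine 0.05
betaine,0.05,0.0498,0.0010,0.99903,141.193,Tab2 betaine 0.05
betaine,0.05,0.0498,0.0050,0.99914,143.212,Tab2 betaine 0.05
betaine,0.05,0.0498,0.0097,0.99927,143.491,Tab2 betaine 0.05
betaine,0.05,0.0498,0.0200,0.99957,142.774,Tab2 betaine 0.05
betaine,0.05,0.0498,0.0294,0.99983,143.048,Tab2 betaine 0.05
des,0.01,0.01,0.0000,0.99799,,Tab2 DES 0.01
des,0.01,0.01,0.0019,0.99817,140.862,Tab2 DES 0.01
des,0.01,0.01,0.0050,0.99846,142.837,Tab2 DES 0.01
des,0.01,0.01,0.0100,0.99894,142.676,Tab2 DES 0.01
des,0.01,0.01,0.0200,0.99987,143.13,Tab2 DES 0.01
des,0.01,0.01,0.0295,1.00075,143.448,Tab2 DES 0.01
des,0.03,0.03,0.0000,0.99897,,Tab2 DES 0.03
des,0.03,0.03,0.0010,0.99901,142.559,Tab2 DES 0.03
des,0.03,0.03,0.0050,0.99917,142.225,Tab2 DES 0.03
des,0.03,0.03,0.0099,0.99936,142.777,Tab2 DES 0.03
des,0.03,0.03,0.0200,0.99975,143.141,Tab2 DES 0.03
des,0.03,0.03,0.0296,1.0001,143.644,Tab2 DES 0.03
des,0.05,0.05,0.0000,1.00005,,Tab2 DES 0.05
des,0.05,0.05,0.0010,1.00009,142.356,Tab2 DES 0.05
des,0.05,0.05,0.0050,1.00025,142.379,Tab2 DES 0.05
des,0.05,0.05,0.0099,1.00043,143.470,Tab2 DES 0.05
des,0.05,0.05,0.0193,1.00079,143.504,Tab2 DES 0.05
des,0.05,0.05,0.0298,1.00117,143.911,Tab2 DES 0.05
il,0.01,0.01,0.0000,0.99896,,Tab2 IL 0.01
il,0.01,0.01,0.0010,0.99899,140.271,Tab2 IL 0.01
il,0.01,0.01,0.0050,0.99911,141.349,Tab2 IL 0.01
il,0.01,0.01,0.0099,0.99926,141.155,Tab2 IL 0.01
il,0.01,0.01,0.0198,0.99955,141.527,Tab2 IL 0.01
il,0.01,0.01,0.0301,0.99984,141.905,Tab2 IL 0.01
il,0.03,0.03,0.0000,0.99961,,Tab2 IL 0.03
il,0.03,0.03,0.0010,0.99964,140.274,Tab2 IL 0.03
il,0.03,0.03,0.0049,0.99975,142.776,Tab2 IL 0.03
il,0.03,0.03,0.0099,0.99989,142.913,Tab2 IL 0.03
il,0.03,0.03,0.0203,1.00018,143.115,Tab2 IL 0.03
il,0.03,0.03,0.0299,1.00044,143.396,Tab2 IL 0.03
il,0.05,0.05,0.0000,1.00007,,Tab2 IL 0.05
il,0.05,0.05,0.0010,1.00010,140.790,Tab2 IL 0.05
il,0.05,0.05,0.0049,1.00021,142.518,Tab2 IL 0.05
il,0.05,0.05,0.0100,1.00034,144.090,Tab2 IL 0.05
il,0.05,0.05,0.0199,1.00062,143.493,Tab2 IL 0.05
il,0.05,0.05,0.0289,1.00085,144.151,Tab2 IL 0.05
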
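# Masson-fit parameters for gabapentin in aqueous betaine-based media at 298 K:
# standard partial molar volume vphi0 (cm^3/mol), slope sv (cm^3 mol^-2 kg),
# their printed uncertainties, and the printed residual standard deviation.
system,solvent_molality,vphi0,vphi0_se,sv,sv_se,sigma,provenance
betaine,0.0098,138.677,0.050,64.835,0.300,0.04,Tab3 betaine
betaine,0.0297,142.010,0.015,31.385,0.631,0.02,Tab3 betaine
betaine,0.0501,142.916,0.040,8.232,0.800,0.09,Tab3 betaine
des,0.0103,141.695,0.054,67.432,0.333,0.07,Tab3 DES
des,0.0299,142.292,0.075,131.835,0.160,0.10,Tab3 DES
des,0.0501,142.407,0.030,39.798,0.894,0.04,Tab3 DES
il,0.0103,140.664,0.070,43.886,0.796,0.01,Tab3 IL
il,0.0294,141.481,0.093,76.856,0.213,0.03,Tab3 IL
il,0.0496,141.791,0.137,93.956,0.931,0.08,Tab3 IL
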
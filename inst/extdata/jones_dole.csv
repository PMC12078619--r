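# Printed Jones-Dole B coefficients for gabapentin in aqueous betaine-based
# media at 298 K. The source prints B under a dm^(3/2) mol^(-1/2) header (the
# A-coefficient units); values are stored here under the conventional B units
# dm^3/mol. B magnitudes are not recoverable from the 3-d.p. viscosities.
system,solvent_molality,B,B_se,sigma_eta,provenance
betaine,0.0099,0.850,0.03,0.01,Tab7 betaine
betaine,0.0298,0.842,0.04,0.06,Tab7 betaine
betaine,0.0496,0.843,0.09,0.09,Tab7 betaine
des,0.0103,1.762,0.13,0.06,Tab7 DES
des,0.0300,0.850,0.09,0.07,Tab7 DES
des,0.0504,-0.275,0.02,0.01,Tab7 DES
il,0.0093,2.009,0.31,0.03,Tab7 IL
il,0.0306,-0.156,0.06,0.04,Tab7 IL
il,0.0493,-2.704,0.13,0.09,Tab7 IL
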
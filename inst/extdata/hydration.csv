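# Electrostriction hydration numbers of gabapentin in aqueous betaine-based
# media at 298 K, as printed.
system,solvent_molality,nh,provenance
betaine,0.0100,3.556,Tab5 betaine
betaine,0.0300,2.546,Tab5 betaine
betaine,0.0500,2.271,Tab5 betaine
des,0.0100,2.641,Tab5 DES
des,0.0300,2.460,Tab5 DES
des,0.0500,2.425,Tab5 DES
il,0.0100,2.954,Tab5 IL
il,0.0300,2.706,Tab5 IL
il,0.0500,2.612,Tab5 IL
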
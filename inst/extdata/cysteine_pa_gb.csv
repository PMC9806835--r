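# Proton affinities (0 and 298.15 K), auxiliary corrections and gas-phase
# basicities (298.15 K) per protonation site of cysteine.
# units: kcal/mol; rows are lowest-conformer pairs (I-I_X) and Boltzmann mixtures
pair,site,flavor,e_qz_f12b,d_t,d_q,d_core,d_rel,d_e_e,d_zpe,d_h0,d_h298,d_g298
I-I_N,N,lowest-conformer,222.89,-0.03,-0.01,0.10,0.03,222.98,-8.49,214.49,215.79,208.44
I-I_O,O,lowest-conformer,208.57,0.02,-0.04,0.05,0.02,208.62,-7.45,201.17,202.74,194.56
I-I_S,S,lowest-conformer,198.22,-0.03,0.01,-0.06,0.05,198.18,-5.46,192.72,194.02,186.86
average-N,N,mixture,223.60,-0.03,-0.01,0.10,0.04,223.69,-8.73,214.96,216.39,208.21
average-O,O,mixture,209.47,0.02,-0.04,0.04,0.02,209.51,-7.67,201.83,203.55,194.16
average-S,S,mixture,199.13,-0.04,0.02,-0.06,0.06,199.10,-5.79,193.31,194.74,186.40
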
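Cocktail chemostat run configuration
S0 (CFU/mL), 1000000
fRA fRB fRAB, 0, 0, 0
psi psiRA psiRB psiRAB (/h), 0.7, 0.7, 0.7, 0.7
K (ug/mL), 5
epsilon (ug/cell), 2e-06
gamma (/h), 0
uA uB (/cell division), 0, 0
sigma rho (/min), 0, 0
C0 Cin (ug/mL), 100, 100
omega (/h), 0.2
deltaA lA betaA phiA (mL/min min PFU/cell /h), 1e-10, 30, 100, 0
Phage A additions (h PFU/mL), 0, 100000000
deltaB lB betaB phiB (mL/min min PFU/cell /h), 1e-10, 20, 100, 0
Phage B additions (h PFU/mL)
Primary adsorption, Standard
Secondary adsorption, Uninfected
Mutation mode, Deterministic
Refuge mode, Off
Round below one, FALSE
Log10 output, FALSE
Step size (s), 60
Duration (h), 200
Seed, 1
Output parameters: 1 2 3 4 5 6 7 8 9 10 11 12 13 14 15 16 
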
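# RNA:RNA nearest-neighbor stack free energies, dG37 kcal/mol.
# Watson-Crick stacks: Freier et al. 1986 duplex parameters (symmetrized).
# Stacks containing a G:U wobble pair carry coarse uniform values
# (-0.5 one wobble, -0.3 two wobbles): an approximation, documented in the
# package methods vignette. Duplex initiation penalty: +3.4 kcal/mol.
# Key orientation: XY/ZW = 5-prime XY 3-prime on the probe paired
# antiparallel with 3-prime ZW 5-prime on the target (X:Z and Y:W pair).
stack	dG_kcal_mol
initiation	3.4
AA/UU	-0.9
AU/UA	-0.9
AG/UC	-1.7
AC/UG	-2.1
AG/UU	-0.5
AU/UG	-0.5
UA/AU	-1.1
UU/AA	-0.9
UG/AC	-1.8
UC/AG	-2.3
UG/AU	-0.5
UU/AG	-0.5
GA/CU	-2.3
GU/CA	-2.1
GG/CC	-2.9
GC/CG	-3.4
GG/CU	-0.5
GU/CG	-0.5
CA/GU	-1.8
CU/GA	-1.7
CG/GC	-2.0
CC/GG	-2.9
CG/GU	-0.5
CU/GG	-0.5
GA/UU	-0.5
GU/UA	-0.5
GG/UC	-0.5
GC/UG	-0.5
GG/UU	-0.3
GU/UG	-0.3
UA/GU	-0.5
UU/GA	-0.5
UG/GC	-0.5
UC/GG	-0.5
UG/GU	-0.3
UU/GG	-0.3
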
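# SantaLucia (1998) unified nearest-neighbor thermodynamic parameter set
# for DNA/DNA duplexes. Proc Natl Acad Sci USA 95:1460-1465, Table 1.
# Units: dH_kcal_mol in kcal/mol, dS_cal_molK in cal/(mol K).
# The 10 unique stacks are expanded to all 16 dinucleotides by strand
# symmetry (a stack and its reverse complement share one parameter pair).
# Reserved rows:
#   INIT_AT - duplex initiation term per terminal A.T pair
#   INIT_GC - duplex initiation term per terminal G.C pair
#   SYM     - symmetry correction, applied once to self-complementary duplexes
# Melting temperature (this package, documented here for provenance):
#   Tm(1M Na+) [K] = 1000*dH / (dS + R*ln(CT/x)),  R = 1.9872 cal/(mol K),
#   CT = total strand concentration, x = 4 (non-self-complementary) or 1.
# Monovalent salt correction (Owczarzy et al. 2004, Biochemistry 43:3537,
# eq. 22), applied to the reciprocal temperature:
#   1/Tm(Na+) = 1/Tm(1M) + (4.29*fGC - 3.95)*1e-5*ln[Na+]
#               + 9.40e-6*(ln[Na+])^2
stack	dH_kcal_mol	dS_cal_molK
AA	-7.9	-22.2
AC	-8.4	-22.4
AG	-7.8	-21.0
AT	-7.2	-20.4
CA	-8.5	-22.7
CC	-8.0	-19.9
CG	-10.6	-27.2
CT	-7.8	-21.0
GA	-8.2	-22.2
GC	-9.8	-24.4
GG	-8.0	-19.9
GT	-8.4	-22.4
TA	-7.2	-21.3
TC	-8.2	-22.2
TG	-8.5	-22.7
TT	-7.9	-22.2
INIT_AT	2.3	4.1
INIT_GC	0.1	-2.8
SYM	0	-1.4
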
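# RNA/RNA Watson-Crick nearest-neighbor free-energy increments, Delta G(37 C),
# kcal/mol. Values from Xia et al. (1998) Biochemistry 37:14719-14735,
# expanded from the 10 unique duplex steps to all 16 dinucleotide keys read
# 5'->3' on one strand (the paired strand is the exact complement, so e.g.
# key GU equals the published AC/GU value).
# Replace this file to use a different published parameter set; the schema is
# two tab-separated columns (step, dg_kcal_mol) plus the header directives.
#init_dg=4.09
#terminal_au=0.45
step	dg_kcal_mol
AA	-0.93
AC	-2.24
AG	-2.08
AU	-1.10
CA	-2.11
CC	-3.26
CG	-2.36
CU	-2.08
GA	-2.35
GC	-3.42
GG	-3.26
GU	-2.24
UA	-1.33
UC	-2.35
UG	-2.11
UU	-0.93
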
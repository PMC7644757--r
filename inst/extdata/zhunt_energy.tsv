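# Dinucleotide B-Z transition free energies (kcal/mol per dinucleotide step).
# Literature-derived defaults following the energetics used by sequence-based
# Z-DNA propensity scoring: each dinucleotide carries the energy of its more
# favourable syn/anti conformer assignment; alternating purine-pyrimidine
# steps are cheapest (CG/GC), out-of-alternation steps carry graded penalties.
# This file is a user-replaceable configuration input; replace the values to
# use a different parameterisation.
# bz_junction	5.0
# zz_junction	4.0
dinucleotide	energy
AA	4.4
AC	1.3
AG	3.4
AT	5.6
CA	1.3
CC	2.4
CG	0.7
CT	3.4
GA	3.4
GC	0.7
GG	2.4
GT	1.3
TA	2.5
TC	3.4
TG	1.3
TT	4.4
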
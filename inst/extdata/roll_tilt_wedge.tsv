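# Dinucleotide wedge-model roll/tilt angles (degrees), strand-symmetric:
# the reverse-complement step carries the same roll and the negated tilt.
step	roll_deg	tilt_deg
AA	-5.4	-0.5
AC	-2.5	-2.7
AG	-1.0	-1.6
AT	-7.3	0.0
CA	6.8	0.4
CC	1.3	0.6
CG	4.6	0.0
CT	-1.0	1.6
GA	2.0	-1.7
GC	-4.0	0.0
GG	1.3	-0.6
GT	-2.5	2.7
TA	8.0	0.0
TC	2.0	1.7
TG	6.8	-0.4
TT	-5.4	0.5
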
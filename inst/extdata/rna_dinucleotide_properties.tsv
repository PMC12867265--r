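# Six A-form RNA base-step (dinucleotide) physicochemical indices:
# Shift, Slide, Rise (angstrom) and Tilt, Roll, Twist (degrees), MD-derived
# literature values for RNA duplex steps. The autocovariance and pseudo
# dinucleotide composition descriptors standardize each column to mean 0 and
# (population) variance 1 over the 16 dinucleotides before use, so only the
# relative pattern matters. The table is swappable: pass any table with the
# same layout to dac()/pse_dnc().
dinucleotide	Shift	Slide	Rise	Tilt	Roll	Twist
AA	-0.08	-1.27	3.18	-0.8	7.0	31
AC	0.23	-1.43	3.24	0.8	4.8	32
AG	-0.04	-1.50	3.30	0.5	8.5	30
AU	-0.06	-1.36	3.24	1.1	7.1	33
CA	0.11	-1.46	3.09	1.0	9.9	31
CC	-0.01	-1.78	3.32	0.3	8.7	32
CG	0.30	-1.89	3.30	-0.1	12.1	27
CU	-0.01	-1.43	3.29	0.6	7.3	32
GA	0.07	-1.70	3.38	-1.3	9.4	32
GC	0.07	-1.39	3.22	0.0	6.1	35
GG	-0.01	-1.78	3.32	0.3	12.1	32
GU	0.23	-1.43	3.24	0.8	4.8	32
UA	-0.02	-1.45	3.26	-0.2	10.7	32
UC	0.07	-1.70	3.38	-1.3	9.4	32
UG	0.11	-1.46	3.09	1.0	9.9	31
UU	-0.08	-1.27	3.18	-0.8	7.0	31
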
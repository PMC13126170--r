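# Per-amino-acid physicochemical properties used for signature featurisation.
# Raw values; min-max normalisation to [0,1] per column is applied at load.
# Columns (AAindex accessions where applicable):
#   WOLS870101/02/03  z-scale principal properties z1/z2/z3 (Wold et al. 1987)
#   NEU1, NEU2, NEU3  hydrophobicity slots; the original Neumaier scales are
#                     not publicly resolvable, so these columns are SYNTHETIC
#                     stand-ins filled with three documented public scales:
#                     NEU1 = Kyte-Doolittle hydropathy, NEU2 = Hopp-Woods
#                     hydrophilicity, NEU3 = Eisenberg consensus
#                     hydrophobicity. Override via property_table() to use
#                     other scales.
#   TSAJ990101        residue volume (Tsai et al. 1999)
#   FAUJ880109        number of hydrogen-bond donors (Fauchere et al. 1988)
#   GRAR740102        polarity (Grantham 1974)
#   RADA880108        mean polarity (Radzicka & Wolfenden 1988)
#   ZIMJ680103        polarity (Zimmerman et al. 1968)
#   CHOP780201/02/03  alpha-helix / beta-sheet / beta-turn propensity
#                     (Chou & Fasman 1978)
#   ZIMJ680104        isoelectric point (Zimmerman et al. 1968)
aa	WOLS870101	NEU1	NEU2	NEU3	WOLS870102	TSAJ990101	WOLS870103	FAUJ880109	GRAR740102	RADA880108	ZIMJ680103	CHOP780201	CHOP780202	CHOP780203	ZIMJ680104
A	0.07	1.8	-0.5	0.62	-1.73	89.3	0.09	0	8.1	-0.06	0.00	1.42	0.83	0.66	6.00
C	0.71	2.5	-1.0	0.29	-0.97	102.5	4.13	1	5.5	1.36	1.48	0.70	1.19	1.19	5.05
D	3.64	-3.5	3.0	-0.90	1.13	114.4	2.36	1	13.0	-0.80	49.70	1.01	0.54	1.46	2.77
E	3.08	-3.5	3.0	-0.74	0.39	138.8	-0.07	1	12.3	-0.77	49.90	1.51	0.37	0.74	3.22
F	-4.92	2.8	-2.5	1.19	1.30	190.8	0.45	0	5.2	1.27	0.35	1.13	1.38	0.60	5.48
G	2.23	-0.4	0.0	0.48	-5.36	63.8	0.30	0	9.0	-0.41	0.00	0.57	0.75	1.56	5.97
H	2.41	-3.2	-0.5	-0.40	1.74	157.5	1.11	1	10.4	0.49	51.60	1.00	0.87	0.95	7.59
I	-4.44	4.5	-1.8	1.38	-1.68	163.0	-1.03	0	5.2	1.31	0.13	1.08	1.60	0.47	6.02
K	2.84	-3.9	3.0	-1.50	1.41	165.1	-3.14	2	11.3	-1.18	49.50	1.16	0.74	1.01	9.74
L	-4.19	3.8	-1.8	1.06	-1.03	163.1	-0.98	0	4.9	1.21	0.13	1.21	1.30	0.59	5.98
M	-2.49	1.9	-1.3	0.64	-0.27	165.8	-0.41	0	5.7	1.27	1.43	1.45	1.05	0.60	5.74
N	3.22	-3.5	0.2	-0.78	1.45	122.4	0.84	2	11.6	-0.48	3.38	0.67	0.89	1.56	5.41
P	-1.22	-1.6	0.0	0.12	0.88	121.6	2.23	0	8.0	0.00	1.58	0.57	0.55	1.52	6.30
Q	2.18	-3.5	0.2	-0.85	0.53	146.9	-1.14	2	10.5	-0.73	3.53	1.11	1.10	0.98	5.65
R	2.88	-4.5	3.0	-2.53	2.52	190.3	-3.44	4	10.5	-0.84	52.00	0.98	0.93	0.95	10.76
S	1.96	-0.8	0.3	-0.18	-1.63	94.2	0.57	1	9.2	-0.50	1.67	0.77	0.75	1.43	5.68
T	0.92	-0.7	-0.4	-0.05	-2.09	119.6	-1.40	1	8.6	-0.27	1.66	0.83	1.19	0.96	5.66
V	-2.69	4.2	-1.5	1.08	-2.53	138.2	-1.29	0	5.9	1.09	0.13	1.06	1.70	0.50	5.96
W	-4.75	-0.9	-3.4	0.81	3.65	226.4	0.85	1	5.4	0.88	2.10	1.08	1.37	0.96	5.89
Y	-1.39	-1.3	-2.3	0.26	2.32	194.6	0.01	1	6.2	0.33	1.61	0.69	1.47	1.14	5.66
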
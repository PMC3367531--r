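A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	-0.36	-0.43	 0.17	 0.17	-0.46	-0.14	 0.14	-0.63	 0.21	-0.56	-0.37	 0.17	-0.02	 0.17	 0.27	-0.10	-0.11	-0.60	-0.09	-0.05
C	-0.43	-0.50	 0.10	 0.10	-0.53	-0.21	 0.07	-0.70	 0.14	-0.63	-0.44	 0.10	-0.09	 0.10	 0.20	-0.17	-0.18	-0.67	-0.16	-0.12
D	 0.17	 0.10	 0.70	 0.70	 0.07	 0.39	 0.67	-0.10	 0.74	-0.03	 0.16	 0.70	 0.51	 0.70	 0.80	 0.43	 0.42	-0.07	 0.44	 0.48
E	 0.17	 0.10	 0.70	 0.70	 0.07	 0.39	 0.67	-0.10	 0.74	-0.03	 0.16	 0.70	 0.51	 0.70	 0.80	 0.43	 0.42	-0.07	 0.44	 0.48
F	-0.46	-0.53	 0.07	 0.07	-0.56	-0.24	 0.04	-0.73	 0.11	-0.66	-0.47	 0.07	-0.12	 0.07	 0.17	-0.20	-0.21	-0.70	-0.19	-0.15
G	-0.14	-0.21	 0.39	 0.39	-0.24	 0.08	 0.36	-0.41	 0.43	-0.34	-0.15	 0.39	 0.20	 0.39	 0.49	 0.12	 0.11	-0.38	 0.13	 0.17
H	 0.14	 0.07	 0.67	 0.67	 0.04	 0.36	 0.64	-0.13	 0.71	-0.06	 0.13	 0.67	 0.48	 0.67	 0.77	 0.40	 0.39	-0.10	 0.41	 0.45
I	-0.63	-0.70	-0.10	-0.10	-0.73	-0.41	-0.13	-0.90	-0.06	-0.83	-0.64	-0.10	-0.29	-0.10	 0.00	-0.37	-0.38	-0.87	-0.36	-0.32
K	 0.21	 0.14	 0.74	 0.74	 0.11	 0.43	 0.71	-0.06	 0.78	 0.01	 0.20	 0.74	 0.55	 0.74	 0.84	 0.47	 0.46	-0.03	 0.48	 0.52
L	-0.56	-0.63	-0.03	-0.03	-0.66	-0.34	-0.06	-0.83	 0.01	-0.76	-0.57	-0.03	-0.22	-0.03	 0.07	-0.30	-0.31	-0.80	-0.29	-0.25
M	-0.37	-0.44	 0.16	 0.16	-0.47	-0.15	 0.13	-0.64	 0.20	-0.57	-0.38	 0.16	-0.03	 0.16	 0.26	-0.11	-0.12	-0.61	-0.10	-0.06
N	 0.17	 0.10	 0.70	 0.70	 0.07	 0.39	 0.67	-0.10	 0.74	-0.03	 0.16	 0.70	 0.51	 0.70	 0.80	 0.43	 0.42	-0.07	 0.44	 0.48
P	-0.02	-0.09	 0.51	 0.51	-0.12	 0.20	 0.48	-0.29	 0.55	-0.22	-0.03	 0.51	 0.32	 0.51	 0.61	 0.24	 0.23	-0.26	 0.25	 0.29
Q	 0.17	 0.10	 0.70	 0.70	 0.07	 0.39	 0.67	-0.10	 0.74	-0.03	 0.16	 0.70	 0.51	 0.70	 0.80	 0.43	 0.42	-0.07	 0.44	 0.48
R	 0.27	 0.20	 0.80	 0.80	 0.17	 0.49	 0.77	 0.00	 0.84	 0.07	 0.26	 0.80	 0.61	 0.80	 0.90	 0.53	 0.52	 0.03	 0.54	 0.58
S	-0.10	-0.17	 0.43	 0.43	-0.20	 0.12	 0.40	-0.37	 0.47	-0.30	-0.11	 0.43	 0.24	 0.43	 0.53	 0.16	 0.15	-0.34	 0.17	 0.21
T	-0.11	-0.18	 0.42	 0.42	-0.21	 0.11	 0.39	-0.38	 0.46	-0.31	-0.12	 0.42	 0.23	 0.42	 0.52	 0.15	 0.14	-0.35	 0.16	 0.20
V	-0.60	-0.67	-0.07	-0.07	-0.70	-0.38	-0.10	-0.87	-0.03	-0.80	-0.61	-0.07	-0.26	-0.07	 0.03	-0.34	-0.35	-0.84	-0.33	-0.29
W	-0.09	-0.16	 0.44	 0.44	-0.19	 0.13	 0.41	-0.36	 0.48	-0.29	-0.10	 0.44	 0.25	 0.44	 0.54	 0.17	 0.16	-0.33	 0.18	 0.22
Y	-0.05	-0.12	 0.48	 0.48	-0.15	 0.17	 0.45	-0.32	 0.52	-0.25	-0.06	 0.48	 0.29	 0.48	 0.58	 0.21	 0.20	-0.29	 0.22	 0.26
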
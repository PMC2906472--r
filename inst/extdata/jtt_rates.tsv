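# JTT amino-acid exchangeability matrix and stationary frequencies
# (Jones, Taylor & Thornton 1992), standard published constants.
aa	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V	freq
A	0	58	54	56	179	35	475	113	646	17	263	49	38	78	43	5	33	21	180	12	0.07674792325
R	58	0	81	57	27	54	9	310	44	528	30	767	4	14	4	18	55	479	65	53	0.05169094831
N	54	81	0	105	36	15	11	29	5	34	10	130	46	223	164	30	8	89	4	536	0.04264495736
D	56	57	105	0	30	194	298	137	74	86	15	112	31	42	53	32	47	10	21	62	0.05154394846
C	179	27	36	30	0	378	45	328	101	58	503	11	9	115	51	10	16	40	47	285	0.0198029802
Q	35	54	15	194	378	0	16	22	64	81	232	7	5	209	18	7	56	245	103	118	0.04075195925
E	475	9	11	298	45	16	0	38	126	391	8	26	59	62	24	45	45	9	10	6	0.06182993817
G	113	310	29	137	328	22	38	0	20	47	70	15	69	323	20	23	33	32	8	10	0.07315192685
H	646	44	5	74	101	64	126	20	0	12	16	4	17	26	119	6	40	961	14	23	0.02294397706
I	17	528	34	86	58	81	391	47	12	0	10	15	23	597	26	6	115	14	43	477	0.05376094624
L	263	30	10	15	503	232	8	70	16	10	0	59	7	9	12	27	73	388	16	35	0.0919039081
K	49	767	130	112	11	7	26	15	4	15	59	0	31	72	9	14	46	248	29	63	0.05867594132
M	38	4	46	31	9	5	59	69	17	23	7	31	0	292	181	5	8	102	226	38	0.02382597617
F	78	14	223	42	115	209	62	323	26	597	9	72	292	0	18	24	573	59	24	12	0.04012595987
P	43	4	164	53	51	18	24	20	119	26	12	9	181	18	0	201	11	25	18	21	0.0509009491
S	5	18	30	32	10	7	45	23	6	6	27	14	5	24	201	0	229	52	323	112	0.06876493124
T	33	55	8	47	16	56	45	33	40	115	73	46	8	573	11	229	0	24	17	71	0.05856494144
W	21	479	89	10	40	245	9	32	961	14	388	248	102	59	25	52	24	0	92	25	0.01426098574
Y	180	65	4	21	47	103	10	8	14	43	16	29	226	24	18	323	17	92	0	16	0.0321019679
V	12	53	536	62	285	118	6	10	23	477	35	63	38	12	21	112	71	25	16	0	0.066004934
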
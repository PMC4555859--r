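# Synthetic 20x20 pairwise contact potential (stand-in, NOT empirical).
# Constructed deterministically from the Fauchere-Pliska side-chain
# hydrophobicity scale and formal residue charges:
#   E0(a,b) = -3.2 H_a H_b - 0.6 (H_a + H_b) + 0.6 q_a q_b
#            + 0.4 (1 - g_a)(1 - g_b) - 0.1
# with H = max(pi, 0)/2.25, g = (pi + 1.01)/3.26, q in {-1, 0, +0.5, +1},
# then scaled so max |E| = 3.477 and rounded to 3 decimals.
	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	-0.142	-0.652	0.029	0.022	-0.755	-0.014	-0.068	-0.759	0.042	-0.718	-0.523	0.020	-0.312	-0.002	0.043	-0.012	-0.122	-0.519	-0.945	-0.412
C	-0.652	-1.856	-0.332	-0.335	-2.100	-0.348	-0.475	-2.110	-0.328	-2.012	-1.552	-0.336	-1.053	-0.344	-0.327	-0.347	-0.603	-1.542	-2.550	-1.288
D	0.029	-0.332	0.652	0.640	-0.406	0.120	-0.150	-0.409	-0.256	-0.379	-0.241	0.173	-0.091	0.140	-0.255	0.124	0.044	-0.238	-0.541	-0.162
E	0.022	-0.335	0.640	0.629	-0.407	0.112	-0.158	-0.410	-0.269	-0.381	-0.245	0.162	-0.097	0.130	-0.267	0.115	0.036	-0.242	-0.541	-0.167
F	-0.755	-2.100	-0.406	-0.407	-2.374	-0.416	-0.558	-2.385	-0.403	-2.275	-1.761	-0.408	-1.203	-0.413	-0.402	-0.415	-0.700	-1.750	-2.877	-1.466
G	-0.014	-0.348	0.120	0.112	-0.416	0.070	0.035	-0.419	0.135	-0.392	-0.264	0.109	-0.126	0.084	0.136	0.073	-0.001	-0.261	-0.541	-0.191
H	-0.068	-0.475	-0.150	-0.158	-0.558	0.035	0.108	-0.561	0.328	-0.528	-0.373	0.072	-0.204	0.048	0.329	0.037	-0.051	-0.369	-0.711	-0.283
I	-0.759	-2.110	-0.409	-0.410	-2.385	-0.419	-0.561	-2.396	-0.406	-2.286	-1.770	-0.411	-1.209	-0.416	-0.405	-0.418	-0.704	-1.759	-2.890	-1.473
K	0.042	-0.328	-0.256	-0.269	-0.403	0.135	0.328	-0.406	0.692	-0.376	-0.235	0.191	-0.081	0.155	0.694	0.139	0.057	-0.232	-0.541	-0.154
L	-0.718	-2.012	-0.379	-0.381	-2.275	-0.392	-0.528	-2.286	-0.376	-2.181	-1.686	-0.382	-1.149	-0.388	-0.375	-0.391	-0.665	-1.675	-2.759	-1.402
M	-0.523	-1.552	-0.241	-0.245	-1.761	-0.264	-0.373	-1.770	-0.235	-1.686	-1.293	-0.246	-0.866	-0.257	-0.234	-0.263	-0.481	-1.284	-2.146	-1.067
N	0.020	-0.336	0.173	0.162	-0.408	0.109	0.072	-0.411	0.191	-0.382	-0.246	0.159	-0.099	0.127	0.193	0.113	0.034	-0.243	-0.541	-0.168
P	-0.312	-1.053	-0.091	-0.097	-1.203	-0.126	-0.204	-1.209	-0.081	-1.149	-0.866	-0.099	-0.559	-0.116	-0.081	-0.124	-0.282	-0.860	-1.480	-0.704
Q	-0.002	-0.344	0.140	0.130	-0.413	0.084	0.048	-0.416	0.155	-0.388	-0.257	0.127	-0.116	0.100	0.157	0.087	0.012	-0.255	-0.541	-0.182
R	0.043	-0.327	-0.255	-0.267	-0.402	0.136	0.329	-0.405	0.694	-0.375	-0.234	0.193	-0.081	0.157	0.695	0.140	0.058	-0.231	-0.541	-0.153
S	-0.012	-0.347	0.124	0.115	-0.415	0.073	0.037	-0.418	0.139	-0.391	-0.263	0.113	-0.124	0.087	0.140	0.075	0.002	-0.260	-0.541	-0.189
T	-0.122	-0.603	0.044	0.036	-0.700	-0.001	-0.051	-0.704	0.057	-0.665	-0.481	0.034	-0.282	0.012	0.058	0.002	-0.102	-0.478	-0.880	-0.376
V	-0.519	-1.542	-0.238	-0.242	-1.750	-0.261	-0.369	-1.759	-0.232	-1.675	-1.284	-0.243	-0.860	-0.255	-0.231	-0.260	-0.478	-1.276	-2.133	-1.060
W	-0.945	-2.550	-0.541	-0.541	-2.877	-0.541	-0.711	-2.890	-0.541	-2.759	-2.146	-0.541	-1.480	-0.541	-0.541	-0.541	-0.880	-2.133	-3.477	-1.794
Y	-0.412	-1.288	-0.162	-0.167	-1.466	-0.191	-0.283	-1.473	-0.154	-1.402	-1.067	-0.168	-0.704	-0.182	-0.153	-0.189	-0.376	-1.060	-1.794	-0.875
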
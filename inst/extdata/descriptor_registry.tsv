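index	family	name	definition
1	estate	estate_sum	Sum of Kier-Hall electrotopological state indices S_i over heavy atoms
2	estate	estate_mean	Mean of S_i
3	estate	estate_max	Maximum S_i
4	estate	estate_min	Minimum S_i
5	estate	estate_range	max(S_i) - min(S_i)
6	estate	estate_sum_C	Sum of S_i over carbon atoms
7	estate	estate_sum_hetero	Sum of S_i over non-carbon heavy atoms
8	estate	estate_sum_O	Sum of S_i over oxygen atoms
9	estate	estate_sum_N	Sum of S_i over nitrogen atoms
10	estate	estate_sum_halogen	Sum of S_i over F, Cl, Br, I atoms
11	estate	istate_sum	Sum of intrinsic states I_i = ((2/L)^2 dv + 1)/d
12	estate	istate_mean	Mean intrinsic state
13	estate	istate_max	Maximum intrinsic state
14	estate	istate_min	Minimum intrinsic state
15	estate	estate_abs_sum	Sum of |S_i|
16	estate	estate_frac_positive	Fraction of heavy atoms with S_i > 0
17	estate	estate_sum_sq	Sum of S_i^2
18	estate	estate_hetero_mean	Mean S_i over non-carbon heavy atoms (0 if none)
19	vsa	labute_asa	Total Labute-style approximate van der Waals surface area (A^2)
20	vsa	estate_vsa_1	Approximate VSA summed over atoms with S_i in (-Inf, -0.390]
21	vsa	estate_vsa_2	VSA over atoms with S_i in (-0.390, 0.290]
22	vsa	estate_vsa_3	VSA over atoms with S_i in (0.290, 0.717]
23	vsa	estate_vsa_4	VSA over atoms with S_i in (0.717, 1.165]
24	vsa	estate_vsa_5	VSA over atoms with S_i in (1.165, 1.540]
25	vsa	estate_vsa_6	VSA over atoms with S_i in (1.540, 1.807]
26	vsa	estate_vsa_7	VSA over atoms with S_i in (1.807, 2.050]
27	vsa	estate_vsa_8	VSA over atoms with S_i in (2.050, 4.690]
28	vsa	estate_vsa_9	VSA over atoms with S_i in (4.690, 9.170]
29	vsa	estate_vsa_10	VSA over atoms with S_i in (9.170, Inf)
30	vsa	en_vsa_1	VSA over atoms with Pauling electronegativity in (-Inf, 2.10]
31	vsa	en_vsa_2	VSA over atoms with electronegativity in (2.10, 2.60]
32	vsa	en_vsa_3	VSA over atoms with electronegativity in (2.60, 3.00]
33	vsa	en_vsa_4	VSA over atoms with electronegativity in (3.00, 3.50]
34	vsa	en_vsa_5	VSA over atoms with electronegativity in (3.50, 3.90]
35	vsa	en_vsa_6	VSA over atoms with electronegativity in (3.90, Inf)
36	topological	wiener_index	Sum of topological distances over unordered heavy-atom pairs
37	topological	balaban_j	Balaban distance connectivity index J
38	topological	zagreb_m1	First Zagreb index: sum of squared degrees
39	topological	zagreb_m2	Second Zagreb index: sum of degree products over bonds
40	topological	graph_radius	Minimum atom eccentricity
41	topological	graph_diameter	Maximum atom eccentricity
42	topological	eccentric_connectivity	Sum over atoms of eccentricity times degree
43	topological	n_heavy_atoms	Number of heavy atoms
44	topological	n_bonds	Number of heavy-atom bonds
45	topological	n_rings	Cyclomatic number (bonds - atoms + components)
46	topological	kappa1	Kier shape index kappa-1
47	topological	kappa2	Kier shape index kappa-2
48	topological	kappa3	Kier shape index kappa-3
49	topological	kappa1_alpha	Alpha-modified kappa-1 (covalent-radius alpha correction)
50	topological	kappa2_alpha	Alpha-modified kappa-2
51	topological	kappa3_alpha	Alpha-modified kappa-3
52	connectivity	chi0	Randic chi-0: sum of delta^-1/2 over atoms
53	connectivity	chi1	Randic chi-1: sum of (delta_i delta_j)^-1/2 over bonds
54	connectivity	chi2	Chi-2 over simple paths of length 2
55	connectivity	chi3	Chi-3 over simple paths of length 3
56	connectivity	chi4	Chi-4 over simple paths of length 4
57	connectivity	chi0v	Valence chi-0 using Kier-Hall valence delta
58	connectivity	chi1v	Valence chi-1
59	connectivity	chi2v	Valence chi-2
60	connectivity	chi3v	Valence chi-3
61	connectivity	chi4v	Valence chi-4
62	connectivity	mean_randic	chi1 divided by number of bonds (0 if acyclic single atom)
63	connectivity	delta_mean	Mean heavy-atom degree
64	connectivity	deltav_mean	Mean Kier-Hall valence delta
65	connectivity	chi1_per_atom	chi1 divided by number of heavy atoms
66	connectivity	platt_index	Sum over bonds of (delta_i + delta_j - 2)
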
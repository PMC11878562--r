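category	n_total	n_observed	expected	difference_printed	enrichment_printed
Structural constituent of ribosome	20847	1288	5329	-4041	-19.38
Translation	20478	1289	5234	-3945	-19.26
Ribosome	19637	1202	5019	-3817	-19.44
Oxidoreductase activity	20194	1657	5162	-3505	-17.36
Transmembrane transporter activity	21227	2197	5426	-3229	-15.21
Catalytic activity	15857	1728	4053	-2325	-14.66
Heme binding	9111	320	2329	-2009	-22.05
GTPase activity	12561	1209	3211	-2002	-15.94
Iron ion binding	8888	412	2272	-1860	-20.93
Oxidoreductase activity, acting on paired donors	6983	151	1785	-1634	-23.4
Monooxygenase activity	6956	157	1778	-1621	-23.3
Biosynthetic process	6282	536	1606	-1070	-17.03
Pyridoxal phosphate binding	5095	298	1302	-1004	-19.71
Flavin adenine dinucleotide binding	4951	270	1266	-996	-20.12
Cellulose binding	949	729	243	486	51.21
GTPase activator activity	2053	1030	525	505	24.6
Phosphatidylinositol binding	3456	1436	883	553	16
Ubiquitin binding	1994	1095	510	585	29.34
Extracellular region	1865	1110	477	633	33.94
Actin binding	2534	1311	648	663	26.16
ATP-dependent chromatin remodeler activity	3528	1665	902	763	21.63
Protein dimerization activity	5595	2332	1430	902	16.12
Signal transduction	6555	2840	1676	1164	17.76
DNA-binding TF activity, RNA pol.II-specific	5893	2682	1506	1176	19.96
Sequence-specific DNA binding	5526	2839	1413	1426	25.81
Guanyl-nucleotide exchange factor activity	5507	2940	1408	1532	27.82
DNA-binding transcription factor activity	7409	3695	1894	1801	24.31
Nucleus	10908	4918	2788	2130	19.53
RNA binding	26072	10825	6664	4161	15.96
Regulation of DNA-templated transcription	20823	9833	5323	4510	21.66
Protein binding	98107	30654	25077	5577	5.68
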
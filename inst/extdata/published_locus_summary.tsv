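# Published locus-level follow-up summary for 20 replicated breast cancer GWAS
# hits evaluated in an African American case-control consortium.
# One row per (hit, phenotype) pair: the hit's follow-up association p-value,
# the best (minimum-p) marker among all tested catalog variants within 500 kb,
# and the best marker among the preferential-LD candidates with its rank k
# among the rank_n tested variants of the locus. r2 values are haplotype r2
# to the hit in the African reference catalog. in_20_locus_set marks the
# canonical 20-locus accounting (all overall-risk loci plus the two
# subtype-only loci); subtype rows for loci already counted under overall
# risk are provided for completeness but flagged FALSE.
hit_id	phenotype	discovery_population	hit_p	best_overall_id	best_overall_p	best_overall_r2	best_pl_id	best_pl_p	rank_k	rank_n	best_pl_r2	in_20_locus_set
rs4849887	overall	European ancestry	6.85e-03	rs4849899	5.64e-06	0.233	rs4849899	5.64e-06	1	5883	0.233	TRUE
rs13000023	overall	African American	6.13e-04	rs185147777	2.72e-04	0.012	rs113674867	1.15e-03	10	6036	0.951	TRUE
rs16857609	overall	European ancestry	4.16e-03	rs185147777	2.72e-04	0.001	rs78037304	6.13e-03	65	6178	0.054	TRUE
rs13387042	overall	European ancestry	3.65e-02	rs185147777	2.72e-04	0.007	rs56269701	5.73e-04	2	6005	0.391	TRUE
rs10069690	overall	European ancestry	2.40e-03	rs73731716	1.33e-06	0.015	rs73731716	1.33e-06	1	6912	0.015	TRUE
rs1432679	overall	European ancestry	2.58e-03	rs116197733	6.38e-04	0.010	rs60172775	4.48e-03	28	4844	0.821	TRUE
rs9693444	overall	European ancestry	3.39e-02	rs77271190	3.99e-05	0.094	rs77271190	3.99e-05	1	5446	0.094	TRUE
rs1011970	overall	European ancestry	4.73e-02	rs3731213	7.61e-04	0.031	rs143070667	1.22e-03	2	6241	0.026	TRUE
rs2981578	overall	African American	4.99e-06	rs2912778	3.75e-06	0.922	rs143014944	7.46e-04	16	6444	0.025	TRUE
rs2981579	overall	European ancestry	1.30e-03	rs2912778	3.75e-06	0.160	rs2912778	3.75e-06	1	6438	0.160	TRUE
rs1219648	overall	European ancestry	3.24e-02	rs2912778	3.75e-06	0.035	rs2912778	3.75e-06	1	6422	0.035	TRUE
rs2981582	overall	European ancestry	4.38e-02	rs2912778	3.75e-06	0.044	rs2912778	3.75e-06	1	6432	0.044	TRUE
rs3817198	overall	European ancestry	4.72e-02	rs57936908	8.47e-04	0.003	rs74047514	1.07e-02	31	6671	0.041	TRUE
rs609275	overall	African American	1.22e-04	rs115894455	3.52e-05	0.011	rs625625	4.48e-05	4	5751	0.350	TRUE
rs6504950	overall	European ancestry	4.52e-02	rs16955774	1.64e-03	0.003	rs114380381	2.61e-02	44	4580	0.089	TRUE
rs3745185	overall	African American	3.85e-05	rs11668840	1.51e-06	0.155	rs62126227	4.64e-06	5	5593	0.781	TRUE
rs2363956	overall	European ancestry	1.92e-04	rs11668840	1.51e-06	0.519	rs11668840	1.51e-06	1	5558	0.519	TRUE
rs8170	overall	European ancestry	1.36e-03	rs11668840	1.51e-06	0.086	rs62126227	4.64e-06	5	5572	0.034	TRUE
rs13387042	ERpos	European ancestry	2.87e-02	rs56269701	3.51e-05	0.391	rs56269701	3.51e-05	1	6005	0.391	FALSE
rs2981579	ERpos	European ancestry	2.24e-02	rs59100826	9.24e-06	0.001	rs2912778	1.22e-05	2	6438	0.160	FALSE
rs3112572	ERpos	African American	6.45e-03	rs1112135	7.75e-07	0.231	rs35850695	1.33e-05	11	5839	0.036	TRUE
rs3745185	ERpos	African American	8.84e-03	rs10416082	7.96e-05	0.001	rs62126227	1.11e-03	12	5593	0.781	FALSE
rs8170	ERneg	European ancestry	8.38e-03	rs11668840	1.49e-07	0.086	rs62126227	2.94e-04	11	5572	0.034	FALSE
rs2363956	ERneg	European ancestry	1.44e-03	rs11668840	1.49e-07	0.519	rs11668840	1.49e-07	1	5558	0.519	FALSE
rs4245739	ERneg	European ancestry	1.98e-02	rs12405987	4.33e-04	0.005	rs12064622	1.65e-03	4	5109	0.028	TRUE
rs10069690	ERneg	European ancestry	2.47e-07	rs10069690	2.47e-07	1.000	rs6867141	1.31e-05	2	6912	0.067	FALSE
rs1432679	ERneg	European ancestry	2.92e-04	rs12332693	2.50e-04	0.919	rs60172775	5.92e-04	10	4844	0.821	FALSE
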
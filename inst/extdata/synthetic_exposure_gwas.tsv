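rsid	effect_allele	other_allele	beta	se	pval	eaf	n
rs0000001	A	G	-0.152891	0.00334664	0	0.4274	182416
rs0000002	T	G	0.0691563	0.00459563	3.544e-51	0.1533	182416
rs0000003	A	G	0.0169719	0.00489984	0.0005327	0.1314	182416
rs0000004	A	C	0.115152	0.00420101	2.047e-165	0.1923	182416
rs0000005	A	C	-0.0571497	0.00368384	2.805e-54	0.2809	182416
rs0000006	T	C	-0.044471	0.00353768	3.061e-36	0.324	182416
rs0000007	T	G	-0.00802421	0.00350155	0.02193	0.3374	182416
rs0000008	A	C	-0.0556303	0.00446406	1.206e-35	0.1647	182416
rs0000009	A	C	-0.0724706	0.00337442	2.584e-102	0.4037	182416
rs0000010	T	C	-0.0195017	0.00331543	4.051e-09	0.4747	182416
rs0000011	T	C	-0.14063	0.0043695	2.919e-227	0.1738	182416
rs0000012	A	C	-0.0740359	0.00332171	4.776e-110	0.4602	182416
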
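rsid	effect_allele	other_allele	beta	se	pval	eaf	n
rs0000001	T	C	-0.0365038	0.0041262	9.003e-19	0.4274	120000
rs0000002	A	C	0.0205008	0.00566612	0.0002967	0.1533	120000
rs0000003	C	T	-0.00566542	0.00604119	0.3483	0.8686	120000
rs0000004	G	T	-0.0291208	0.00517958	1.885e-08	0.8077	120000
rs0000005	C	A	0.0138981	0.00454194	0.002214	0.7191	120000
rs0000006	G	A	0.00955575	0.00436173	0.02847	0.676	120000
rs0000007	G	T	0.00488397	0.00431719	0.2579	0.6626	120000
rs0000008	A	C	-0.0147675	0.00550391	0.007294	0.1647	120000
rs0000009	G	T	0.0167342	0.00416044	5.765e-05	0.5963	120000
rs0000010	T	C	-0.00133957	0.00408771	0.7431	0.4747	120000
rs0000011	A	G	-0.0453331	0.00538732	3.937e-17	0.1738	120000
rs0000012	A	C	-0.0193435	0.00409545	2.322e-06	0.4602	120000
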
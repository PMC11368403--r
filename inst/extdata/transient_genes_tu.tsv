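gene_id	tu_id	category	product
sll0741	TU3296	oxidoreductase	nifJ pyruvate-ferredoxin/flavodoxin oxidoreductase
sll0743	TU3296	oxidoreductase	hypothetical protein
sll0744	TU3296	oxidoreductase	dihydroorotate dehydrogenase (fumarate)
sll1221	TU1714	oxidoreductase	hoxF bidirectional [NiFe] hydrogenase diaphorase subunit
sll1222	TU1714	oxidoreductase	unknown protein
sll1223	TU1714	oxidoreductase	hoxU bidirectional [NiFe] hydrogenase diaphorase subunit
sll1224	TU1714	oxidoreductase	hoxY NAD-reducing hydrogenase small subunit
sll1225	TU1714	oxidoreductase	unknown protein
sll1226	TU1714	oxidoreductase	hoxH NAD-reducing hydrogenase large subunit
slr1434	TU1089	oxidoreductase	pntB H+-translocating NAD(P) transhydrogenase subunit beta
sll1450	TU1023	transporter	nrtA nitrate/nitrite transport system substrate binding protein
sll1451	TU1023	transporter	nrtB nitrate/nitrite transport system permease protein
sll1452	TU1023	transporter	nrtC nitrate/nitrite transport system ATP binding protein
sll1453	TU1023	transporter	nrtD nitrate/nitrite transport system ATP binding protein
slr1214	TU905	two_component_system	twitching motility response regulator PilG
slr1215	TU907	two_component_system	unknown protein
slr2116	TU1673	glycosyl_transferase	spsA spore coat polysaccharide biosynthesis protein
sll1009	TU491	protease	frpC iron-regulated protein
slr1523	TU1659	insertion_sequence	transposase
sll1985	TU1589	insertion_sequence	transposase
sll7001	NA	insertion_sequence	transposase
sll7003	TU7001	insertion_sequence	toxin FitB
ssl0172	TU3163	insertion_sequence	transposase
slr1260	TU1446	other	hypothetical protein
slr0668	TU3532	other	unknown protein
slr5127	TU5127	other	unknown protein
sll0710	TU97	other	unknown protein
sll1307	TU1224	other	unknown protein
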
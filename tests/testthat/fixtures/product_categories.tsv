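product	category
carbon monoxide dehydrogenase accessory protein CooC	cooC
CooC family protein	cooC
nickel-binding protein CooT	cooT
nickel chaperone CooJ	cooJ
formate dehydrogenase subunit alpha	one_carbon_pool
acetyl-CoA decarbonylase/synthase complex subunit beta	one_carbon_pool
formate--tetrahydrofolate ligase	one_carbon_pool
methylenetetrahydrofolate reductase	one_carbon_pool
5-methyltetrahydrofolate:corrinoid/iron-sulfur protein methyltransferase	one_carbon_pool
4Fe-4S dicluster domain-containing ferredoxin	ferredoxin
iron-sulfur cluster-binding protein CooF	fes_protein
[2Fe-2S] binding protein	fes_protein
Fe-S cluster assembly protein SufB	fes_protein
energy-converting hydrogenase subunit EchE	hydrogenase
[NiFe] hydrogenase large subunit	hydrogenase
hydrogenase maturation protease HycI	hydrogenase_maturase
hydrogenase expression/formation protein HypE	hydrogenase_maturase
NAD(P)H-dependent FAD-containing oxidoreductase	nadp_fad_oxidoreductase
NADH-quinone oxidoreductase subunit E	nadp_fad_oxidoreductase
FAD-dependent oxidoreductase	nadp_fad_oxidoreductase
LysR family transcriptional regulator	transcription_regulation
RNA polymerase sigma factor SigA	transcription_regulation
two-component system response regulator	other_regulation
signal transduction histidine kinase	other_regulation
ABC transporter ATP-binding protein	abc_transporter
branched-chain amino acid ABC transporter permease	abc_transporter
MFS transporter	transporter
Na+/H+ antiporter	transporter
hypothetical protein	other
DUF1284 domain-containing protein	other
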
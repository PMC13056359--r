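category	priority	pattern	scope
cooC	10	cooc	any
cooT	11	coot	any
cooJ	12	cooj	any
hydrogenase_maturase	20	hyp[abcdef]\b|\bhydrogenase[- ](maturation|formation|expression)|maturation of hydrogenase	any
one_carbon_pool	30	formate dehydrogenase|tetrahydrofolate|corrinoid|acetyl-coa (synthase|decarbonylase)|decarbonylase(/| )synthase|serine hydroxymethyltransferase|glycine cleavage|formaldehyde-activating|methanol dehydrogenase|wood.?ljungdahl	any
ferredoxin	40	ferredoxin	any
nadp_fad_oxidoreductase	45	(nad|fad|fmn|flavin).{0,40}oxidoreductase|oxidoreductase.{0,40}(nad|fad|flavin)	any
abc_transporter	50	abc[- ]?transporter|abc[- ]type|atp[- ]binding cassette	any
transcription_regulation	55	transcription(al)?.{0,20}(regulator|repressor|activator|factor)|sigma.?factor|rna polymerase sigma	any
hydrogenase	60	\bhydrogenase	any
fes_protein	65	iron[- ]sul(f|ph)ur|fe[- ]?s (cluster|protein)|\[?[24]fe[- ]?[24]s\]?|\bcoof\b|\bnifu\b|\bhesb\b	any
other_regulation	70	regulator|regulatory|two[- ]component|histidine kinase|anti[- ]?sigma|signal transduction	any
transporter	80	transporter|permease|antiporter|symporter|efflux|transport (protein|system)|uptake system	any
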
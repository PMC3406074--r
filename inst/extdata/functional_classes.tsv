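fragment	class
catalase	ANTIOXIDANT
peroxiredoxin	ANTIOXIDANT
glutathione peroxidase	ANTIOXIDANT
glutathione transferase	TRANSFERASE
glutathione s-transferase	TRANSFERASE
methyltransferase	TRANSFERASE
sulfotransferase	TRANSFERASE
acetyltransferase	TRANSFERASE
glutamyltransferase	TRANSFERASE
glutamyltranspeptidase	TRANSFERASE
epoxide hydrolase	HYDROLASE
carboxylesterase	HYDROLASE
glucuronidase	HYDROLASE
oxidoreductase	OXIDOREDUCTASE
dehydrogenase	OXIDOREDUCTASE
reductase	OXIDOREDUCTASE
oxidase	OXIDOREDUCTASE
cytochrome p450	OXIDOREDUCTASE
synthase	OXIDOREDUCTASE
peroxidase	OXIDOREDUCTASE
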
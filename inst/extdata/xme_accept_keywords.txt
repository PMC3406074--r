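# XME accept list: one name fragment per line.
# A protein name containing any fragment (case-insensitive, after
# normalization) is accepted as a putative xenobiotic-metabolising enzyme,
# unless a word filter or the reject list fires first.
3-Hydroxyacyl-CoA dehydrogenase
acyl-coenzyme A synthetase ACSM1
adrenodoxin
alcohol dehydrogenase
aldehyde dehydrogenase
aldehyde oxidase
aldo-keto reductase
amine oxidase
arylacetamide deacetylase-like 1
bifunctional 3′-phosphoadenosine 5′-phosphosulfate synthase
carbonyl reductase
carboxylesterase
catalase
catechol-O-methyltransferase
catechol O-methyltransferase
cytochrome P450
dehydrogenase/reductase SDR family member
dopamine beta-hydroxylase
epoxide hydrolase
gamma-glutamyl carboxylase
gamma-glutamyltranspeptidase
glucuronidase
glutamate–cysteine ligase
glutathione peroxidase
glutathione transferase
glutathione synthetase
hepatocyte nuclear factor 4-alpha
histamine N-methyltransferase
hydroxysteroid dehydrogenase
kynureninase
lactoperoxidase
long-chain-fatty-acid–CoA ligase 1
monooxygenase
N-acetyltransferase
NAD(P)H dehydrogenase [quinone] 1
NAD(P) transhydrogenase, mitochondrial
nicotinamide N-methyltransferase
nitric oxide synthase
nuclear receptor subfamily 1 group I member 2
peroxiredoxin
prostaglandin G/H synthase
prostacyclin synthase
protein S100-A12
quinone oxidoreductase
steryl-sulfatase
sulfotransferase
thiopurine S-methyltransferase
thiosulfate sulfurtransferase
thyroid peroxidase
trans-1,2-dihydrobenzene-1,2-diol dehydrogenase
thromboxane-A synthase
xanthine dehydrogenase
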
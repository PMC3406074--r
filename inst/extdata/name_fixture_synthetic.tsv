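name	expected_outcome	expected_fragment
cytochrome P450 2E1	accepted	cytochrome p450
glutathione transferase T1	accepted	glutathione transferase
epoxide hydrolase 1	accepted	epoxide hydrolase
aldehyde dehydrogenase 2	accepted	aldehyde dehydrogenase
carbonyl reductase [NADPH] 1	accepted	carbonyl reductase
membrane primary amine oxidase	accepted	amine oxidase
NADH-ubiquinone oxidoreductase	accepted	quinone oxidoreductase
catechol O-methyltransferase	accepted	catechol o-methyltransferase
peroxiredoxin-6	accepted	peroxiredoxin
sulfotransferase 1A1	accepted	sulfotransferase
glucose-6-phosphate dehydrogenase	rejected-by-reject-list	glucose-6-phosphate dehydrogenase
protein-glutamine gamma-glutamyltransferase	rejected-by-reject-list	protein-glutamine gamma-glutamyltransferase
dolichyl-diphosphooligosaccharide-protein glycosyltransferase 48 kDa subunit	rejected-by-reject-list	dolichyl-diphosphooligosaccharide-protein glycosyltransferase
heparan sulfate proteoglycan core protein	rejected-by-reject-list	heparan
carbohydrate sulfotransferase 1	rejected-by-reject-list	carbohydrate
hypothetical protein LOC644739	filtered-by-word	hypothetical
aldo-keto reductase family 1 member C3-like protein	filtered-by-word	like
cytochrome P450 2B6-like protein	filtered-by-word	like
hypothetical oxidoreductase YMR226C	filtered-by-word	hypothetical
amine oxidase-like protein 2	filtered-by-word	like
keratin, type I cytoskeletal 14	no-keyword-match	
actin, cytoplasmic 1	no-keyword-match	
serum albumin	no-keyword-match	
vimentin	no-keyword-match	
annexin A2	no-keyword-match	
histone H4	no-keyword-match	
collagen alpha-1(I) chain	no-keyword-match	
elongation factor 1-alpha 1	no-keyword-match	
heat shock protein beta-1	no-keyword-match	
pyruvate kinase PKM	no-keyword-match	
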
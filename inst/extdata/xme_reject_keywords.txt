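# XME reject list: a name containing any fragment is eliminated even when
# it also contains an accept fragment (reject precedence).
carbohydrate
heparan
glucose-6-phosphate dehydrogenase
protein-glutamine gamma-glutamyltransferase
dolichyl-diphosphooligosaccharide-protein glycosyltransferase
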
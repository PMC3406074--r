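# Whole-word name filters applied before any keyword matching: a protein
# name containing one of these words (on word boundaries) is dropped.
hypothetical
like
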
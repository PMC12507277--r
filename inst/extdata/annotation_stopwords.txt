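protein
proteins
bacteria
bacterial
putative
hypothetical
predicted
probable
conserved
uncharacterized
domain
family
like
containing
associated
related
type
subunit
precursor
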
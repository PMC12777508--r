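residue	formula
A	C10H13N5O4
C	C9H13N3O5
G	C10H13N5O5
U	C9H12N2O6
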
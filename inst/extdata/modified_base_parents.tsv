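# Parent mapping for common modified nucleotide components.
# Editable: unlisted components fall back to ring-atom-name matching.
# nucleic_class: DNA or RNA. version: 1
comp_id	parent_base	nucleic_class
DA	A	DNA
DC	C	DNA
DG	G	DNA
DT	T	DNA
DU	U	DNA
A	A	RNA
C	C	RNA
G	G	RNA
U	U	RNA
1MA	A	RNA
2MG	G	RNA
M2G	G	RNA
7MG	G	RNA
OMG	G	RNA
OMC	C	RNA
OMU	U	RNA
5MC	C	RNA
5CM	C	DNA
5MU	T	RNA
PSU	U	RNA
H2U	U	RNA
4SU	U	RNA
I	G	RNA
BRU	U	DNA
5BU	U	DNA
6OG	G	DNA
8OG	G	DNA
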
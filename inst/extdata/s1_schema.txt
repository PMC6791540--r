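# Schema map for the "calliper statistical review" dataset layout
# (multi-operator calliper measurements). Column headers of the published
# supplementary CSV are not documented in the article text: confirm these
# mappings against the file on first use and edit as needed. Units: mm.
study_id: Study
mouse_id: Animal
day: Date
operator_id: Operator
length: Length
width: Width
weight: Weight
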
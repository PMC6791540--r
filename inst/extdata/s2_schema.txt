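# Schema map for the calliper-vs-scan comparison dataset layout (paired
# calliper and 3D-scan measurements, four operators). Confirm the headers
# against the published supplementary CSV on first use. Units: mm, mm^2.
mouse_id: Animal
day: Date
operator_id: Operator
instrument: Method
length: Length
width: Width
height: Height
area: Area
excluded: Excluded
strain: Strain
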
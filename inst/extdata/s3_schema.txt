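# Schema map for the volume-weight comparison dataset layout (volume
# estimates paired with excised tumour weight in grams). Confirm the
# headers against the published supplementary CSV on first use.
mouse_id: Animal
day: Date
operator_id: Operator
instrument: Method
length: Length
width: Width
height: Height
weight: Weight
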
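c-Rel	association;physical association
Tax	physical association
CBP	association
p300	association;direct interaction
IL-2	association
NF-kappaB	physical association
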
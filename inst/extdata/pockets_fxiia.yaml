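# Factor XIIa active-site subsites (chymotrypsin numbering), editable.
# Each pocket lists residue tags (RESNAME + residue number); contact_radius
# (A) applies to all pockets unless overridden per pocket.
contact_radius: 4.5
S1: [ASP189, ALA190, CYS191, SER195, VAL213, SER214, GLY216, GLY219, CYS220]
S1p: [HIS57, CYS42, GLY193, SER195, CYS58]
S2: [HIS57, TYR99, LEU98]
S3: [TRP215, GLY216, GLY219, TYR99]
S4: [LEU98, TYR99, PHE174, TRP215]
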
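# Ligand moiety / CV-atom alias table.
# One row per CV-defining atom: ligand alias, aromatic moiety (I = middle
# ring, II and III = flanking rings), the schematic atom label, the PDB atom
# name in the coordinate file, and whether the atom enters the nine-atom CV
# set. Deposited atom names for PDC (Phen-DC3) and 36A (360A) depend on the
# chemical-component dictionary used by the deposition; fill the `atom`
# column to match your files before analysing deposited complexes. The SYN
# ligand is the package's synthetic planar stand-in and is fully mapped.
ligand	moiety	label	atom	cv
SYN	I	I1	I1	TRUE
SYN	I	I2	I2	TRUE
SYN	I	I3	I3	TRUE
SYN	II	II1	II1	TRUE
SYN	II	II2	II2	TRUE
SYN	II	II3	II3	TRUE
SYN	III	III1	III1	TRUE
SYN	III	III2	III2	TRUE
SYN	III	III3	III3	TRUE
PDC	I	a'	NA	TRUE
PDC	I	b	NA	TRUE
PDC	I	K	NA	TRUE
PDC	II	B	NA	TRUE
PDC	II	C	NA	TRUE
PDC	II	f	NA	TRUE
PDC	III	B'	NA	TRUE
PDC	III	C'	NA	TRUE
PDC	III	f'	NA	TRUE
36A	I	c	NA	TRUE
36A	I	c'	NA	TRUE
36A	I	J	NA	TRUE
36A	II	B	NA	TRUE
36A	II	C	NA	TRUE
36A	II	f	NA	TRUE
36A	III	B'	NA	TRUE
36A	III	C'	NA	TRUE
36A	III	f'	NA	TRUE
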
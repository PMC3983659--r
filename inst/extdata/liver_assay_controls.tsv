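id	coords_hg18	score	location	activity
C1	Chr15:56263227-56263340	-2.22	Intronic (AQP9)	No
C2	Chr6:26030369-26030485	-2.03	Intronic (SLC17A2)	No
C3	Chr22:19494975-19495083	-1.26	Intronic (PI4KA)	No
C4	Chr5:138482622-138482789	-1.67	Intronic (SIL1)	No
C5	Chr9:96485498-96485627	-1.32	Intergenic (50 kbp upstream of FBP1 and C9orf3)	No
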
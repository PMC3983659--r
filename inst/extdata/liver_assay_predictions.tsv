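id	coords_hg18	score	location	activity	chromatin_state
E1	Chr16:30009197-30009301	3.07	Intronic (TBX6)	Yes	No
E7	Chr10:82023332-82023434	2.60	Intergenic (3' UTR of MAT1A)	No	Yes
E2	Chr17:69962796-69962894	2.21	Intergenic (4.5 kb downstream of GPRC5C)	No	No
E8	Chr1:31679030-31679149	1.94	Intronic (SERINC2)	Yes	Yes
E12	Chr3:134934911-134935091	1.81	Intronic (TF)	Yes	Yes
E4	Chr11:72138832-72139119	1.83	Intronic (ARAP1)	Yes	No
E5	Chr17:69957921-69958023	1.30	Intergenic (3' UTR of GPRC5C)	Yes	No
E10	Chr17:69951076-69951329	1.57	Intronic (GPRC5C)	Yes	Yes
E3	Chr11:72162942-72163179	1.47	Intronic (STARD10)	No	No
E9	Chr11:72168912-72169046	1.33	Intronic (STARD10)	No	Yes
E11	Chr11:72166225-72166509	1.36	Intronic (STARD10)	Yes	Yes
E6	Chr17:17439720-17439913	1.04	Intergenic (4 kb upstream of PEMT)	No	No
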
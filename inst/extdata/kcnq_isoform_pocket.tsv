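xKCNQ1_resi	xKCNQ1_resn	element	role	hKCNQ1	hKCNQ2	hKCNQ3	hKCNQ4	hKCNQ5
238	TRP	S4-S5L	principal	W248	-	-	-	-
241	LEU	S4-S5L	principal	L251	-	-	-	-
245	VAL	S4-S5L	principal	V255	-	-	-	-
252	LEU	S5	principal	L262	-	-	-	-
255	THR	S5	principal	T265	-	-	-	-
256	LEU	S5	principal	L266	W236	W	W242	W
333	PRO	S6	principal	P343	-	-	-	-
337	LEU	S6	principal	L347	-	-	-	-
258	ILE	S5'	primed	I268	-	-	-	-
261	LEU	S5'	primed	L271	-	-	-	-
262	GLY	S5'	primed	G272	C242	T	V248	T
265	PHE	S5'	primed	F275	-	-	-	-
322	PHE	S6'	primed	F332	F297	-	F303	-
324	VAL	S6'	primed	V334	-	-	-	-
325	PHE	S6'	primed	F335	I300	L	L306	L
326	ALA	S6'	primed	A336	-	-	-	-
328	SER	S6'	primed	S338	-	-	-	-
329	PHE	S6'	primed	F339	F304	-	-	-
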
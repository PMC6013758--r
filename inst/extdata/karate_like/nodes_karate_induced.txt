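id	Community
n01	F
n02	D
n03	D
n04	E
n05	C
n06	B
n07	A
n08	B
n09	A
n10	A|B
n11	B|D
n12	F
n13	C
n14	A
n15	B
n16	A|B
n17	A
n18	D
n19	A
n20	A
n21	E
n22	E
n23	C
n24	C
n25	A
n26	A|F
n27	D
n28	B|D
n29	A|B
n30	E
n31	C|D
n32	B
n33	F
n34	A
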
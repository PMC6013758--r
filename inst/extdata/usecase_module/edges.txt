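n01	n02
n01	n03
n02	n04
n03	n05
n03	n06
n03	n07
n04	n08
n08	n09
n05	n10
n02	n11
n05	n12
n10	n13
n12	n14
n03	n15
n12	n16
n14	n17
n16	n18
n09	n19
n01	n20
n06	n21
n02	n22
n15	n23
n02	n24
n14	n25
n19	n26
n03	n27
n22	n28
n14	n29
n05	n30
n25	n31
n09	n32
n06	n33
n03	n34
n11	n35
n17	n36
n19	n37
n17	n38
n12	n39
n11	n40
n14	n33
n12	n27
n11	n16
n12	n25
n07	n38
n06	n28
n21	n29
n18	n21
n02	n10
n13	n14
n23	n36
n15	n22
n09	n25
n01	n18
n07	n20
n20	n40
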
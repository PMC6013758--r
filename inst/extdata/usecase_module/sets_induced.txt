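id	Label	URL	Score
GO:0006954	set go:0006954	https://example.org/set/GO:0006954	6.140
GO:0008152	set go:0008152	https://example.org/set/GO:0008152	6.720
GO:0008013	set go:0008013	https://example.org/set/GO:0008013	6.250
GO:0008083	set go:0008083	https://example.org/set/GO:0008083	4.710
GO:0005886	set go:0005886	https://example.org/set/GO:0005886	7.580
mmu04070	set mmu04070	https://example.org/set/mmu04070	0.687
mmu05200	set mmu05200	https://example.org/set/mmu05200	1.920
mmu04520	set mmu04520	https://example.org/set/mmu04520	9.180
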
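id	Name	Score	LogFC	PValue	Module	URL	Symbol	Process	Function	Component	Pathway
n01	n01-protein	-0.979	0.416	0.0291	small	https://example.org/node/n01	GeneN01	GO:0006954			mmu04070
n02	n02-protein	0.513	-0.6	0.0386	small	https://example.org/node/n02	GeneN02	GO:0006954			
n03	n03-protein	-0.957	2.23	0.0425	small	https://example.org/node/n03	GeneN03				mmu05200
n04	n04-protein	1.737	0.637	0.0299	small	https://example.org/node/n04	GeneN04	GO:0006954			
n05	n05-protein	-0.153	-0.903	0.0341	small	https://example.org/node/n05	GeneN05				mmu04520
n06	n06-protein	-1.608	-1.823	0.0144	small	https://example.org/node/n06	GeneN06		GO:0008083		
n07	n07-protein	-2.206	0.935	0.0115	small	https://example.org/node/n07	GeneN07				mmu04070
n08	n08-protein	-2.683	0.24	0.0351		https://example.org/node/n08	GeneN08	GO:0006954			
n09	n09-protein	2.712	0.842	0.00233		https://example.org/node/n09	GeneN09			GO:0005886	
n10	n10-protein	1.796	0.968	0.00307	small	https://example.org/node/n10	GeneN10	GO:0006954			mmu04520
n11	n11-protein	-1.35	1.745	0.0431		https://example.org/node/n11	GeneN11	GO:0008152			
n12	n12-protein	-0.824	1.116	0.0133		https://example.org/node/n12	GeneN12			GO:0005886	mmu04520
n13	n13-protein	0.119	-0.806	0.0401		https://example.org/node/n13	GeneN13	GO:0006954			
n14	n14-protein	-1.579	0.501	0.00948		https://example.org/node/n14	GeneN14			GO:0005886	
n15	n15-protein	-0.166	0.293	0.0227	small	https://example.org/node/n15	GeneN15		GO:0008013		mmu05200
n16	n16-protein	-1.959	0.133	0.019		https://example.org/node/n16	GeneN16	GO:0008152			mmu04520
n17	n17-protein	2.917	-0.388	0.0231		https://example.org/node/n17	GeneN17		GO:0008013		mmu04070
n18	n18-protein	1.604	0.459	0.0221	small	https://example.org/node/n18	GeneN18	GO:0008152			
n19	n19-protein	-0.105	1.457	0.0388		https://example.org/node/n19	GeneN19			GO:0005886	
n20	n20-protein	-1.016	1.147	0.0336		https://example.org/node/n20	GeneN20				mmu04070
n21	n21-protein	-1.872	0.503	0.0258	small	https://example.org/node/n21	GeneN21		GO:0008083	GO:0005886	
n22	n22-protein	-0.591	-0.546	0.0419		https://example.org/node/n22	GeneN22		GO:0008013		
n23	n23-protein	-1.075	-0.857	0.022	small	https://example.org/node/n23	GeneN23		GO:0008013		
n24	n24-protein	-1.495	-1.399	0.0303	small	https://example.org/node/n24	GeneN24	GO:0006954			
n25	n25-protein	0.164	-2.082	0.0345		https://example.org/node/n25	GeneN25			GO:0005886	mmu04520
n26	n26-protein	1.731	2.149	0.0254		https://example.org/node/n26	GeneN26			GO:0005886	
n27	n27-protein	-0.483	-0.434	0.0253	small	https://example.org/node/n27	GeneN27				mmu05200|mmu04520
n28	n28-protein	-2.59	-0.926	0.0192		https://example.org/node/n28	GeneN28		GO:0008013|GO:0008083		
n29	n29-protein	-0.341	1.305	0.0427		https://example.org/node/n29	GeneN29			GO:0005886	
n30	n30-protein	1.051	-1.041	0.0192	small	https://example.org/node/n30	GeneN30				mmu04520
n31	n31-protein	1.509	-0.241	0.0437		https://example.org/node/n31	GeneN31			GO:0005886	
n32	n32-protein	1.929	0.783	0.0434		https://example.org/node/n32	GeneN32			GO:0005886	
n33	n33-protein	-1.528	-0.269	0.0431		https://example.org/node/n33	GeneN33		GO:0008083		
n34	n34-protein	-0.74	0.498	0.0123	small	https://example.org/node/n34	GeneN34				mmu05200
n35	n35-protein	2.083	0.5	0.0215		https://example.org/node/n35	GeneN35	GO:0008152			
n36	n36-protein	1.477	-0.467	0.00844	small	https://example.org/node/n36	GeneN36		GO:0008013		
n37	n37-protein	0.529	-0.8	0.0317		https://example.org/node/n37	GeneN37			GO:0005886	
n38	n38-protein	-2.233	1.513	0.0277		https://example.org/node/n38	GeneN38				mmu04070
n39	n39-protein	-0.631	-1.395	0.0237		https://example.org/node/n39	GeneN39				mmu04520
n40	n40-protein	1.406	-1.912	0.0451		https://example.org/node/n40	GeneN40	GO:0008152			
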
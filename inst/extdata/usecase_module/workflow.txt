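# Enriched-module workflow on the synthetic module fixture:
# import network + typed annotations, scope to the extracted module,
# generate pathway/function groups, annotate and select them, export SVG.
network import path=edges.txt indexColumnSourceInteraction=1 indexColumnTargetInteraction=2
table import firstRowAsColumnNames=true keyColumnIndex=1 startLoadRow=1 dataTypeList=s,s,f,f,f,s,s,s,sl,sl,sl,sl path=nodes_induced.txt
network select nodeList=Module:small
examine generate groups selectedGroupColumns=Function,Pathway
table import firstRowAsColumnNames=true keyColumnIndex=1 startLoadRow=1 path=sets_induced.txt
examine update settings labelColumn=Symbol urlColumn=URL scoreColumn=Score showScore=true selectedGroupColumns=Component,Function
examine select groups selectedGroups=GO:0008013,GO:0008083,mmu04070,mmu05200,mmu04520
examine export path=fig1a.svg
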
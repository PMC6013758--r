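# Community workflow on the synthetic karate-like fixture:
# import GML network + community annotations, select all nodes,
# generate and select the six overlapping communities, export SVG.
network import path=edges_karate.gml indexColumnSourceInteraction=2 indexColumnTargetInteraction=2
table import firstRowAsColumnNames=true keyColumnIndex=1 startLoadRow=1 dataTypeList=s,sl path=nodes_karate_induced.txt
network select nodeList=all
examine generate groups selectedGroupColumns=Community
examine update settings labelColumn=label urlColumn=label showScore=false selectedGroupColumns=Community
examine select groups selectedGroups=A,B,C,D,E,F
examine export path=fig1b.svg
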
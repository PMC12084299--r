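"","panCK","vimentin","CD31","aSMA","CD45","CD8a","CD4","FOXP3","CD20","CD56","CD15","CD68","IL1b","S100A9","CCR7","CXCL13","MMP9","Ki67","SSA","SSB","DNA1"
"panCK",1,0.03,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
"vimentin",0,1,0.03,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
"CD31",0,0,1,0.03,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
"aSMA",0,0,0,1,0.03,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
"CD45",0,0,0,0,1,0.03,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
"CD8a",0,0,0,0,0,1,0.03,0,0,0,0,0,0,0,0,0,0,0,0,0,0
"CD4",0,0,0,0,0,0,1,0.03,0,0,0,0,0,0,0,0,0,0,0,0,0
"FOXP3",0,0,0,0,0,0,0,1,0.03,0,0,0,0,0,0,0,0,0,0,0,0
"CD20",0,0,0,0,0,0,0,0,1,0.03,0,0,0,0,0,0,0,0,0,0,0
"CD56",0,0,0,0,0,0,0,0,0,1,0.03,0,0,0,0,0,0,0,0,0,0
"CD15",0,0,0,0,0,0,0,0,0,0,1,0.03,0,0,0,0,0,0,0,0,0
"CD68",0,0,0,0,0,0,0,0,0,0,0,1,0.03,0,0,0,0,0,0,0,0
"IL1b",0,0,0,0,0,0,0,0,0,0,0,0,1,0.03,0,0,0,0,0,0,0
"S100A9",0,0,0,0,0,0,0,0,0,0,0,0,0,1,0.03,0,0,0,0,0,0
"CCR7",0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0.03,0,0,0,0,0
"CXCL13",0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0.03,0,0,0,0
"MMP9",0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0.03,0,0,0
"Ki67",0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0.03,0,0
"SSA",0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0.03,0
"SSB",0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0.03
"DNA1",0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1
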
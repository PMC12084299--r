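"channel","metal","marker","category"
1,"M141","panCK","lineage"
2,"M142","vimentin","lineage"
3,"M143","CD31","lineage"
4,"M144","aSMA","lineage"
5,"M145","CD45","lineage"
6,"M146","CD8a","lineage"
7,"M147","CD4","lineage"
8,"M148","FOXP3","lineage"
9,"M149","CD20","lineage"
10,"M150","CD56","lineage"
11,"M151","CD15","lineage"
12,"M152","CD68","lineage"
13,"M153","IL1b","functional"
14,"M154","S100A9","functional"
15,"M155","CCR7","functional"
16,"M156","CXCL13","functional"
17,"M157","MMP9","functional"
18,"M158","Ki67","functional"
19,"M159","SSA","pSS_marker"
20,"M160","SSB","pSS_marker"
21,"M161","DNA1","dna"
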
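# Marker-gating annotation rules for the default 21-channel panel.
# Rules are matched in order against cluster mean normalized expression;
# an immune cluster matching more than one immune rule receives the
# fallback label.
fallback: mixed immune
rules:
  - cell_type: epithelial
    positive: [panCK]
    negative: [CD45]
  - cell_type: mesenchymal
    positive: [vimentin]
    negative: [panCK, CD45]
  - cell_type: endothelial
    positive: [CD31]
    negative: [CD45]
  - cell_type: aSMA+ fibroblast
    positive: [aSMA]
    negative: [CD45]
  - cell_type: CD8+ T
    positive: [CD45, CD8a]
    immune: true
  - cell_type: CD4+ T
    positive: [CD45, CD4]
    negative: [FOXP3]
    immune: true
  - cell_type: Treg
    positive: [CD45, FOXP3]
    immune: true
  - cell_type: B
    positive: [CD45, CD20]
    immune: true
  - cell_type: NK
    positive: [CD45, CD56]
    immune: true
  - cell_type: neutrophil
    positive: [CD45, CD15]
    immune: true
  - cell_type: resident macrophage
    positive: [CD45, CD68]
    immune: true
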
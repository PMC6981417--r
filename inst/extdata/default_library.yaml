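# Default ion-library configuration.
# species: Svennerholm symbols (OAc forms are generated via max_acetyl)
# bases:   sphingoid bases; acyls: fatty acids as <carbons>:<double bonds>
# max_dehydrations: global lactone cap (per-species cap still applies)
# max_acetyl: O-acetyl groups per ion
species:
  - GM3
  - GM2
  - GM1
  - LacNAcGM1
  - GD3
  - GD2
  - GD1b
  - GT3
  - GT2
bases:
  - d18:1
acyls:
  - "14:0"
  - "16:0"
  - "18:0"
  - "22:0"
  - "24:0"
  - "24:1"
max_dehydrations: 2
max_acetyl: 1
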
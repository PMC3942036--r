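# Venn comparison definitions: each comparison maps group names to the
# lineage groups (taxonomy.tsv column "lineage") whose concurrent-domain
# sets are unioned.
amorphea_vs_bikonta:
  Amorphea: [Metazoa, Unicellular_Holozoa, Fungi, Apusozoa, Amoebozoa]
  Bikonta: [Embryophyta, Chlorophyta, Rhodophyta, Heterokonta, Alveolata,
            Rhizaria, Haptophyta, Cryptophyta, Excavata]
kingdoms:
  Metazoa: [Metazoa]
  Embryophyta: [Embryophyta]
  Fungi: [Fungi]
holozoa:
  Metazoa: [Metazoa]
  Unicellular_Holozoa: [Unicellular_Holozoa]
  Fungi: [Fungi]
  Amoebozoa: [Amoebozoa]
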
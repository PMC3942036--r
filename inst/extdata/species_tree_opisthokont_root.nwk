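((Fungi,(Ichthyosporea,Corallochytrium,(C_owczarzaki,M_vibrans)Filasterea,(Choanoflagellata,Metazoa)Choanozoa)LHolCA)LOCA,(Apusozoa,(Amoebozoa,((Metamonada,Discoba)Excavata,((Embryophyta,Chlorophyta)Viridiplantae,Rhodophyta)Archaeplastida,(Cryptophyta,(Haptophyta,((Heterokonta,Alveolata)HetAlv,Rhizaria)SAR)HapSAR)CCTH)Bikonta)AltA)AltB)OPROOT;
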
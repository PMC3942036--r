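((Metamonada,Discoba)Excavata,(((Embryophyta,Chlorophyta)Viridiplantae,Rhodophyta)Archaeplastida,(Cryptophyta,(Haptophyta,((Heterokonta,Alveolata)HetAlv,Rhizaria)SAR)HapSAR)CCTH,(Amoebozoa,(Apusozoa,(Fungi,(Ichthyosporea,Corallochytrium,(C_owczarzaki,M_vibrans)Filasterea,(Choanoflagellata,Metazoa)Choanozoa)LHolCA)LOCA)Obazoa)Amorphea)AltC)EXROOT;
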
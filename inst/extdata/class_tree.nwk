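(I,(II,XVIII),((V,Vp),XIX,XXXIII,XI,XXI,XXVII)Vlike,VI,IV,(((III,III-like),XVI),IX,XVII,(XX,XXXIV),(XXV,XXVI),((X,XV),VII),XXII)MyTH4grp,XIII,XIV,XXIII,VIII,XXX,XXXI)classes;
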
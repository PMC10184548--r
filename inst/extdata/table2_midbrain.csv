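taxon,midbrain_mm,medulla_mm,ratio,ratio_digits,source,recomputable
Sinosaurus,50.2,52.5,0.96,2,Xing et al. (2014),TRUE
Majungasaurus,52.8,36.2,1.46,2,Sampson and Witmer (2007),TRUE
Viavenator,49.8,41.7,1.19,2,Paulina-Carabajal and Filippi (2018),TRUE
Baryonyx,61.6,46.9,1.31,2,this study,TRUE
Ceratosuchops,61.1,49.9,1.22,2,this study,TRUE
Allosaurus,58.9,38.6,1.53,2,Witmer and Ridgely (2009),TRUE
Acrocanthosaurus,55.6,44,1.26,2,Franzosa and Rowe (2005),TRUE
Murusraptor,33.5,32,1.05,2,Paulina-Carabajal and Currie (2018),TRUE
Tyrannosaurus,40.7,50.9,0.8,1,Witmer and Ridgely (2009),TRUE
Erlikosaurus,20.4,27.7,0.74,2,Lautenschlager et al. (2012),TRUE
Deinonychus,16.3,20.7,0.79,2,Witmer and Ridgely (2009),TRUE
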
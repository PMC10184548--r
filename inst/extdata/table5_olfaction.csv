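group,taxon,ratio_pct_min,ratio_pct_max,bulb_mm,cerebrum_mm,source,recomputable
Spinosauridae,Ceratosuchops,50.6,50.6,26.4,52.2,this study,TRUE
Ceratosauria,Ceratosaurus,48.1,48.1,NA,NA,Zelenitsky et al. (2009; 2011),FALSE
Ceratosauria,Majungasaurus,48.3,48.3,NA,NA,Zelenitsky et al. (2009; 2011),FALSE
Ceratosauria,Carnotaurus,50,50,NA,NA,Cerroni and Paulina-Carabajal (2019),FALSE
Ceratosauria,Viavenator,57,57,NA,NA,Paulina-Carabajal and Filippi (2018),FALSE
Allosauroidea,Allosaurus,50,51.6,NA,NA,Zelenitsky et al. (2009; 2011),FALSE
Allosauroidea,Acrocanthosaurus,58.1,58.1,NA,NA,Zelenitsky et al. (2009; 2011),FALSE
Allosauroidea,Carcharodontosaurus,56,56,NA,NA,Zelenitsky et al. (2009; 2011),FALSE
Allosauroidea,Giganotosaurus,57.7,57.7,NA,NA,Zelenitsky et al. (2009; 2011),FALSE
Allosauroidea,Sinraptor,55,55,NA,NA,Cerroni and Paulina-Carabajal (2019),FALSE
Tyrannosauroidea,Dilong,27,27,NA,NA,Zelenitsky et al. (2009; 2011),FALSE
Tyrannosauroidea,Tarbosaurus,65.1,67.4,NA,NA,Zelenitsky et al. (2009; 2011),FALSE
Tyrannosauroidea,Tyrannosaurus,68.3,71,NA,NA,Zelenitsky et al. (2009; 2011),FALSE
Tyrannosauroidea,Murusraptor,45,50,NA,NA,Paulina-Carabajal and Currie (2018),FALSE
Ornithomimosauria,Ornithomimosauria,28.2,32.5,NA,NA,Zelenitsky et al. (2009; 2011),FALSE
Oviraptoridae,Oviraptoridae,31.5,31.5,NA,NA,Zelenitsky et al. (2009; 2011),FALSE
Dromaeosauridae,Dromaeosauridae,28.5,36,NA,NA,Zelenitsky et al. (2009; 2011),FALSE
Troodontidae,Troodontidae,32.6,33.5,NA,NA,Zelenitsky et al. (2009; 2011),FALSE
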
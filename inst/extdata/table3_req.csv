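taxon,ev_cm3_min,ev_cm3_max,ev37_cm3_min,ev37_cm3_max,ev50_cm3_min,ev50_cm3_max,mbd_g_min,mbd_g_max,req37_min,req37_max,req37_digits,req50_min,req50_max,req50_digits,recomputable,source,note
Baryonyx,150.5,150.5,55.7,55.7,75.3,75.3,2011000,2011000,1.2,1.2,1,1.6,1.6,1,TRUE,this study,NA
Carnotaurus,169.8,169.8,62.8,62.8,84.9,84.9,1419000,1743000,1.4,1.6,1,1.9,2.2,1,TRUE,Cerroni and Paulina-Carabajal (2019),NA
Majungasaurus,106.4,106.4,39.4,39.4,53.2,53.2,1130000,1130000,1.14,1.14,2,1.54,1.54,2,TRUE,Cerroni and Paulina-Carabajal (2019),NA
Ceratosaurus,NA,NA,NA,NA,NA,NA,NA,NA,1.2,1.2,1,1.7,1.7,1,FALSE,Cerroni and Paulina-Carabajal (2019),REQ printed without endocast volume or body mass; literature values only
Allosaurus,169,188,62.5,69.5,84.5,93.9,1400000,2300000,1.3,1.8,1,1.8,2.4,1,FALSE,Cerroni and Paulina-Carabajal (2019),printed REQ range does not rederive from any pairing of the printed volume and mass endpoints
Sinraptor,95,95,35.1,35.1,47.5,47.5,1700000,1700000,0.8,0.8,1,1.1,1.1,1,TRUE,Cerroni and Paulina-Carabajal (2019),NA
Giganotosaurus,275,275,101.7,101.7,137.5,137.5,7000000,7000000,1.1,1.1,1,1.4,1.4,1,FALSE,Cerroni and Paulina-Carabajal (2019),37% and 50% volume columns misreported in the source; stored as printed
Murusraptor,148.2,148.2,54.8,54.8,74.1,74.1,1551000,1551000,1.33,1.33,2,1.8,1.8,1,TRUE,Cerroni and Paulina-Carabajal (2019),NA
Tyrannosaurus,414.2,414.2,153.2,153.2,207.1,207.1,5654000,7000000,1.6,1.8,1,2.2,2.5,1,FALSE,Cerroni and Paulina-Carabajal (2019),printed 37% volume 153.2 truncates 153.254; REQ values as printed
Gorgosaurus,128.9,128.9,47.7,47.7,64.5,64.5,1100000,1100000,1.4,1.4,1,1.9,1.9,1,TRUE,Cerroni and Paulina-Carabajal (2019),NA
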
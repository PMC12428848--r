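label,status,accession,primer_pair,fragment_bp,intron_bp
S2,known,AY587562.1,EM-PC2consFD/EM-PC3consRD,895,706
S2,known,AY587562.1,Pru-C2/Amy-C5,1096,706
S8,known,AY884212.1,Pru-C2/Amy-C5,827,410
S8,known,AY884212.1,Pru-C2/PCE-R,573,409
S8,known,AY884212.1,AS1II/Amy-C5,928,411
S9,known,AY853594.1,Pru-C2/Amy-C5,885,467
S10,known,AY846872.1,EM-PC2consFD/EM-PC3consRD,266,180
S11,known,DQ868316.1,EM-PC2consFD/EM-PC3consRD,464,275
S11,known,DQ868316.1,Pru-C2/Amy-C5,672,275
S12,known,DQ870628.1,EM-PC2consFD/EM-PC3consRD,359,171
S13,known,DQ870629.1,EM-PC2consFD/EM-PC3consRD,401,212
S14,known,DQ870630.1,EM-PC2consFD/EM-PC3consRD,493,305
S14a,known,GU574199.1,EM-PC2consFD/EM-PC3consRD,495,309
S15,known,DQ870631.1,EM-PC2consFD/EM-PC3consRD,469,283
S16,known,DQ870631.1,EM-PC2consFD/EM-PC3consRD,481,292
S16,known,DQ870631.1,Pru-C2/Amy-C5,700,292
S17,known,DQ270001.1,EM-PC2consFD/EM-PC3consRD,657,461
S18-1,known,DQ270000.1,EM-PC2consFD/EM-PC3consRD,307,108
S18-2,known,DQ870634.1,EM-PC2consFD/EM-PC3consRD,1337,1148
S18-2,known,DQ870634.1,Pru-C2/Amy-C5,1546,1148
S20,known,EF160078.1,EM-PC2consFD/EM-PC3consRD,1936,1749
S23,known,EU037262.1,EM-PC2consFD/EM-PC3consRD,693,505
S24,known,EU037263.1,EM-PC2consFD/EM-PC3consRD,357,168
S24,known,EU037263.1,Pru-C2/Amy-C5,588,168
S25,known,EU037264.1,EM-PC2consFD/EM-PC3consRD,772,583
S25,known,EU037264.1,Pru-C2/Amy-C5,994,584
S26,known,EU037265.1,Pru-C2/PCE-R,416,289
S28,known,EU836684.1,Pru-C2/Amy-C5,1352,946
S30,known,EF185301.1,Pru-C2/Amy-C5,726,285
S35,known,GU574196.1,EM-PC2consFD/EM-PC3consRD,312,124
S36,known,GU574198.1,Pru-C2/Amy-C5,718,299
S40-1,known,GU354239.1,EM-PC2consFD/EM-PC3consRD,539,353
S40-1,known,GU354239.1,Pru-C2/Amy-C5,749,353
S40-2,known,HQ342870.1,AS1II/Amy-C5,542,164
S44,known,HQ342874.1,Pru-C2/PCE-R,635,464
S49,known,HQ342879.1,Pru-C2/Amy-C5,653,212
S52,known,KF951503.2,EM-PC2consFD/EM-PC3consRD,1296,1111
S52,known,KF951503.2,Pru-C2/Amy-C5,1512,1110
S53,known,KF975455.2,Pru-C2/Amy-C5,965,508
S54,known,KT223013.1,PaConsII-F/PaConsII-R,1296,891
S66,known,JQ317152.1,Pru-C2/Amy-C5,704,308
S93,novel,PV206781,EM-PC2consFD/EM-PC3consRD,273,90
S94,novel,PV206782,EM-PC2consFD/EM-PC3consRD,502,319
S95,novel,PV206783,Pru-C2/Amy-C5,683,275
S96,novel,PV206784,Pru-C2/Amy-C5,575,173
S97,novel,PV206785,Pru-C2/Amy-C5,746,458
S98,novel,PV206791,Pru-C2/Amy-C5,871,460
S99,novel,PV206786,Pru-C2/Amy-C5,884,460
S100,novel,PV206792,Pru-C2/Amy-C5,924,522
S101,novel,PV206787,Pru-C2/Amy-C5,1348,928
S102,novel,PV206793,Pru-C2/Amy-C5,1416,996
S103,novel,PV206788,Pru-C2/Amy-C5,1452,1044
S104,novel,PV206789,Pru-C2/Amy-C5,1466,1035
S105,novel,PV206794,Pru-C2/Amy-C5,1625,1214
S106,novel,PV206790,EM-PC2consFD/EM-PC3consRD,533,346
S107,novel,PV206780,EM-PC2consFD/EM-PC3consRD,1227,1046
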
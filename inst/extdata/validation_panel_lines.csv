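accession,other_reference,donor,pct_homozygosity,pct_heterozygosity
NV153-1,ig12658,NIAB,98.73,1.27
NV639-1,Hedin,GAUG,98.61,1.39
NV643-3,Albus,NIAB,97.85,2.15
NV644-1,Kasztelan,NIAB,92.56,7.44
NV648-2,BPL10,ICARDA,98.87,1.13
NV656-3,ig101942,NIAB,99.37,0.63
NV657-2,INRA-29H,IFAPA,99.11,0.89
NV658-2,CGN07715 cf-3,GAUG,99.24,0.76
NV662-1,VF136,IFAPA,97.22,2.78
NV713-1,Cote d'Or,GAUG,98.36,1.64
NV714-1,Hiverna,GAUG,99.25,0.75
NV715-1,Webo,GAUG,99.10,0.90
NV716-1,Wibo,GAUG,99.36,0.64
NV717-1,L79-79,GAUG,99.50,0.50
NV718-1,L977-88,GAUG,99.75,0.25
NV719-1,L979-S1,GAUG,99.62,0.38
NV720-1,Bourdon,GAUG,99.24,0.76
NV721-1,Arrisot,GAUG,98.99,1.01
NV722-1,Banner,GAUG,98.99,1.01
NV723-1,Bulldog,GAUG,99.12,0.88
NV724-1,Pietranera,GAUG,99.24,0.76
NV725-1,GIZA3-2,GAUG,99.36,0.64
NV726-1,GIZA402,GAUG,99.11,0.89
NV727-1,BPL4628,ICARDA,98.86,1.14
NV728-1,TW,ICARDA,99.11,0.89
NV729-1,VF6,ICARDA,98.58,1.42
NV730-1,ILB4347-4,ICARDA,99.24,0.76
NV731-1,ILB4347-3,ICARDA,99.50,0.50
NV732-1,BPL710,ICARDA,97.83,2.17
NV733-1,NA112,ICARDA,99.12,0.88
NV734-1,ILB938,UoH,99.62,0.38
NV735-1,Melodie,UoH,98.99,1.01
NV736-1,Aurora,UoH,98.22,1.78
NV737-1,CRB285,INRA,97.11,2.89
NV738-1,CRB2516,INRA,99.21,0.79
NV739-1,CRB2702,INRA,94.63,5.37
NV740-1,CRB100107,INRA,99.60,0.40
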
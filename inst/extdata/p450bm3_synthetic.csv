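genotype,trait,mean,sem,n
---,ce,11.5,0.2,2
---,conv,8,0.15,2
---,ddg,0,0.05,2
---,ncr,-10,0.5,2
---,pfr,10,0.1,2
---,sel,50,0.5,2
---,ttf,11,0.8,2
---,ttn,110,1.5,2
I--,ce,9.5,0.2,2
I--,conv,6.5,0.15,2
I--,ddg,-2.5,0.13,2
I--,ncr,-14,0.5,2
I--,pfr,9,0.1,2
I--,sel,26.7276,0.5,2
I--,ttf,7,0.8,2
I--,ttn,94,1.5,2
-I-,ce,10.9,0.2,2
-I-,conv,7.5,0.15,2
-I-,ddg,-2.7,0.13,2
-I-,ncr,-8,0.5,2
-I-,pfr,12,0.1,2
-I-,sel,25.1775,0.5,2
-I-,ttf,11,0.8,2
-I-,ttn,114,1.5,2
--I,ce,21.6,0.2,2
--I,conv,9.5,0.15,2
--I,ddg,1.75,0.13,2
--I,ncr,-5,0.5,2
--I,pfr,14,0.1,2
--I,sel,66.9504,0.5,2
--I,ttf,21,0.8,2
--I,ttn,120,1.5,2
II-,ce,11.9,0.2,2
II-,conv,6.4,0.15,2
II-,ddg,-2.4,0.1,2
II-,ncr,-13.3,0.5,2
II-,pfr,12,0.1,2
II-,sel,27.525,0.5,2
II-,ttf,9,0.8,2
II-,ttn,107,1.5,2
I-I,ce,12.6,0.2,2
I-I,conv,10,0.15,2
I-I,ddg,1.85,0.1,2
I-I,ncr,14,0.5,2
I-I,pfr,12.8,0.1,2
I-I,sel,67.8368,0.5,2
I-I,ttf,24,0.8,2
I-I,ttn,142,1.5,2
-II,ce,37,0.2,2
-II,conv,34,0.15,2
-II,ddg,4.65,0.1,2
-II,ncr,88,0.5,2
-II,pfr,55,0.1,2
-II,sel,86.7127,0.5,2
-II,ttf,72,0.8,2
-II,ttn,614,1.5,2
III,ce,37,0.2,2
III,conv,34.5,0.15,2
III,ddg,5.6,0,2
III,ncr,276,0.5,2
III,pfr,124,0.1,2
III,sel,90.5425,0.5,2
III,ttf,158,0.8,2
III,ttn,656,1.5,2
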
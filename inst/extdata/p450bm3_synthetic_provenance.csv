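genotype,trait,provenance,note
---,ce,assumed,free choice below the 37% plateau
---,conv,assumed,free choice in the ~6-10% range
---,ddg,anchored,1:1 product ratio -> 0 kJ/mol
---,ncr,assumed,leak exceeds consumption: negative corrected rate
---,pfr,assumed,"free choice, ~10 1/min scale"
---,sel,solved,"exactly logistic(ddg/RT), percent"
---,ttf,anchored,TTF series start 11
---,ttn,assumed,"free choice, TTN scale ~100"
I--,ce,assumed,free choice below the 37% plateau
I--,conv,assumed,free choice in the ~6-10% range
I--,ddg,assumed,"singles constrained to sum -3.45 kJ/mol; R47I,T49I negative"
I--,ncr,assumed,leak exceeds consumption: negative corrected rate
I--,pfr,assumed,"free choice, ~10 1/min scale"
I--,sel,solved,"exactly logistic(ddg/RT), percent"
I--,ttf,solved,solved from interaction identities
I--,ttn,assumed,"free choice, TTN scale ~100"
-I-,ce,assumed,free choice below the 37% plateau
-I-,conv,assumed,free choice in the ~6-10% range
-I-,ddg,assumed,"singles constrained to sum -3.45 kJ/mol; R47I,T49I negative"
-I-,ncr,assumed,leak exceeds consumption: negative corrected rate
-I-,pfr,assumed,"free choice, ~10 1/min scale"
-I-,sel,solved,"exactly logistic(ddg/RT), percent"
-I-,ttf,solved,solved from interaction identities
-I-,ttn,assumed,"free choice, TTN scale ~100"
--I,ce,solved,from interaction identities
--I,conv,assumed,free choice in the ~6-10% range
--I,ddg,assumed,Y51I positive; see singles sum
--I,ncr,assumed,leak exceeds consumption: negative corrected rate
--I,pfr,assumed,"free choice, ~10 1/min scale"
--I,sel,solved,"exactly logistic(ddg/RT), percent"
--I,ttf,anchored,TTF series 11 -> 21
--I,ttn,assumed,"free choice, TTN scale ~100"
II-,ce,solved,from interaction identities
II-,conv,solved,from binary interaction identities
II-,ddg,solved,from binary interaction identities
II-,ncr,solved,from binary interaction identities
II-,pfr,solved,from interaction identities
II-,sel,solved,"exactly logistic(ddg/RT), percent"
II-,ttf,solved,solved from interaction identities
II-,ttn,solved,from interaction identities
I-I,ce,solved,from interaction identities
I-I,conv,solved,from binary interaction identities
I-I,ddg,solved,from binary interaction identities
I-I,ncr,solved,from interaction identities
I-I,pfr,solved,from interaction identities
I-I,sel,solved,"exactly logistic(ddg/RT), percent"
I-I,ttf,solved,solved from interaction identities
I-I,ttn,solved,from interaction identities
-II,ce,anchored,37% coupling efficiency plateau
-II,conv,solved,from binary interaction identities
-II,ddg,solved,from binary interaction identities
-II,ncr,solved,from interaction identities
-II,pfr,solved,from interaction identities
-II,sel,solved,"exactly logistic(ddg/RT), percent"
-II,ttf,anchored,TTF series 21 -> 72
-II,ttn,solved,from interaction identities
III,ce,anchored,37% coupling efficiency plateau
III,conv,anchored,~35% conversion of the full variant
III,ddg,anchored,5.6 kJ/mol for the full variant
III,ncr,solved,from interaction identities
III,pfr,solved,from interaction identities
III,sel,solved,"exactly logistic(ddg/RT), percent"
III,ttf,anchored,TTF series 72 -> 158
III,ttn,solved,from interaction identities
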
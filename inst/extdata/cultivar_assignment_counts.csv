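cultivar,origin,use,colour,well_n,well_kk,nora,total
Moscato bianco (Muscat à petits grains blancs),Greece/Italy/France,W,white,232,11,2,245
Vitouska,Slovenia/Italy (Friuli),W,white,154,8,5,167
Cannonanu (Garnacha tinta),Italy (Sardinia),W,red,81,29,51,161
Bayan shirei,Azerbaijan,W/T,white,123,3,14,140
Claretta di Sardegna (Bourboulenc),Italy (Sardinia),W,white,121,4,0,125
Gregu nieddu,Italy (Sardinia),W,red,83,19,9,111
Forgiarin (Forzarin),Italy (Friuli),W,red,88,2,0,90
Trebbiano abruzzese,Italy (central south),W,white,83,1,5,89
Lambrusco viadanese,Italy (central),W,red,86,2,0,88
Aptiche aga,Armenia,W/T,red,66,3,0,69
Malvasia di Casorzo,Italy (north),W,red,58,3,3,64
Caddiu bianco,Italy (Sardinia),W,white,51,5,2,58
Grenache blanc (Garnacha blanca),France,W,white,21,4,21,46
Malvasia bianca lunga,Italy (Tuscany),W,white,40,0,0,40
Pignolo,Italy (Friuli),W,red,16,17,4,37
Guleiman kara,Uzbekistan,ND,red,18,3,13,34
Uvalino,Italy (north),W,red,2,8,19,29
Arvesiniadu,Italy (Sardinia),W,white,24,4,0,28
Chaouch blanc,Turkey,T,white,13,6,2,21
Schiava,Italy (north),W,red,13,7,0,20
Malvasia di Sardegna (Malvasia Dubrovacka),Italy (Sardinia),W,white,4,15,1,20
Impigno,Italy (south),W,white,16,1,0,17
Kypreiko,Greece,W,red,16,1,0,17
Tzitzka,Georgia,W/T,white,9,4,4,17
Licronaxu,Italy (Sardinia),W/T,white,13,1,2,16
Culupuntu,Italy (Sardinia),W,white,0,0,11,11
Coda di volpe bianca,Italy (Campania),W/T,white,8,0,2,10
Albourla rose,Ukraine,W/T,red,8,1,1,10
Mazzese,Italy (Tuscany),W,red,0,5,5,10
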
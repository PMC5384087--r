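species,previous_name,molecular,morphology,areas,elev_mean,elev_low,elev_high
alcmena,,FALSE,TRUE,A,1100,1050,1200
aletta,,TRUE,TRUE,ABCE,693,50,1450
alicia,,FALSE,TRUE,I,1235,1100,1490
alida,,TRUE,TRUE,CDE,1933,800,3000
andreas,alissa,TRUE,TRUE,CDI,1337,750,1860
alissa,,TRUE,TRUE,CE,1227,300,2000
artena,,TRUE,TRUE,ACDE,1365,900,2060
calgiria,,FALSE,TRUE,D,1719,1300,2970
carlia,,TRUE,TRUE,H,910,100,1700
cotytto,,TRUE,TRUE,AE,776,80,1455
donella,,TRUE,TRUE,AB,386,20,825
euritea,,TRUE,TRUE,H,553,30,1250
forsteri,,TRUE,TRUE,F,632,182,1350
fulvimargo,,TRUE,TRUE,A,1455,1110,2060
fumida,,FALSE,TRUE,AC,870,450,1000
gertschi,,TRUE,TRUE,C,950,500,1000
glauca,,FALSE,TRUE,C,1230,800,1400
granica,,TRUE,TRUE,C,1929,1500,2250
hara,,TRUE,TRUE,ACDE,1474,600,2400
inania,,TRUE,TRUE,CE,1659,1200,2100
latilla,,TRUE,TRUE,ACE,1012,170,1925
laura,,TRUE,TRUE,CE,1088,800,1400
lonera,,TRUE,TRUE,A,1198,500,1575
medellina,,TRUE,TRUE,C,1707,1380,2000
obscuratus,,TRUE,TRUE,AB,257,30,700
olimba,,TRUE,TRUE,D,1403,1000,1525
oneida,,TRUE,TRUE,CE,1992,1250,2650
asopo,oneida,TRUE,TRUE,E,900,900,900
ozia,,TRUE,TRUE,CDE,1446,600,2500
parva,,TRUE,TRUE,A,842,200,2060
peteri,,FALSE,TRUE,I,1040,1040,1040
picta,,TRUE,TRUE,ACE,1104,350,2060
dispar,picta,TRUE,FALSE,C,1500,1300,1800
primula,,TRUE,TRUE,BFG,389,65,1050
rufocincta,,TRUE,TRUE,A,998,210,1500
sao,,TRUE,TRUE,FG,332,100,800
serrata,,TRUE,TRUE,CD,2091,1700,2300
sexpunctata,,TRUE,TRUE,D,1265,635,1500
simplex,,TRUE,TRUE,A,1544,1100,2300
tamina,,TRUE,TRUE,CD,1667,800,2075
thabena,teresita,TRUE,TRUE,CDE,1670,790,2400
teresita,,TRUE,TRUE,C,1184,1000,1350
ticida,,TRUE,TRUE,CDE,1784,1200,2400
tucuna,,TRUE,TRUE,F,777,100,1350
veia_EAST,veia,TRUE,TRUE,CE,1662,1000,2400
veia_WEST,veia,TRUE,TRUE,C,1729,1300,2150
vestilla,,TRUE,TRUE,F,398,100,900
alina,zerlina,TRUE,TRUE,CD,1784,700,2500
zerlina,,TRUE,TRUE,CE,1473,635,2000
spnov1,,TRUE,TRUE,E,1730,1730,1730
spnov2,,TRUE,TRUE,C,1765,850,2530
spnov3,,TRUE,TRUE,C,1898,1700,2030
spnov4,,TRUE,TRUE,A,656,500,700
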
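year,source,value_millions
1,McEvedy & Jones,170
1,Kremer,170
1,Biraben,252
1,Blaxter,255
1,Clark,256
1,Haub,300
1,UN 1999,300
200,McEvedy & Jones,190
200,Kremer,190
200,Biraben,257
200,Blaxter,256
400,McEvedy & Jones,190
400,Kremer,190
400,Biraben,206
400,Blaxter,206
400,Clark,254
500,McEvedy & Jones,190
500,Biraben,207
600,McEvedy & Jones,200
600,Kremer,200
600,Biraben,208
600,Blaxter,206
600,Clark,237
700,McEvedy & Jones,210
700,Biraben,206
700,Blaxter,207
800,McEvedy & Jones,220
800,Kremer,220
800,Biraben,224
800,Blaxter,224
800,Clark,261
900,McEvedy & Jones,240
900,Biraben,222
900,Blaxter,226
1000,McEvedy & Jones,265
1000,Kremer,265
1000,Biraben,253
1000,Blaxter,254
1000,Clark,280
1000,UN 1999,310
1100,McEvedy & Jones,320
1100,Kremer,320
1100,Biraben,299
1100,Blaxter,301
1200,McEvedy & Jones,360
1200,Kremer,360
1200,Biraben,400
1200,Blaxter,400
1200,Clark,384
1200,Haub,450
1250,Biraben,417
1250,UN 1999,400
1300,McEvedy & Jones,360
1300,Kremer,360
1300,Biraben,431
1300,Blaxter,432
1340,Biraben,442
1340,Clark,378
1400,McEvedy & Jones,350
1400,Kremer,350
1400,Biraben,375
1400,Blaxter,374
1500,McEvedy & Jones,425
1500,Kremer,425
1500,Biraben,461
1500,Blaxter,460
1500,Clark,427
1500,UN 1999,500
1600,McEvedy & Jones,545
1600,Kremer,545
1600,Biraben,578
1600,Blaxter,579
1600,Clark,498
1650,McEvedy & Jones,545
1650,Kremer,545
1650,Clark,516
1650,Haub,500
1700,McEvedy & Jones,610
1700,Kremer,610
1700,Biraben,680
1700,Blaxter,679
1700,Clark,641
1750,McEvedy & Jones,720
1750,Kremer,720
1750,Biraben,771
1750,Blaxter,770
1750,Clark,731
1750,Haub,795
1750,UN 1999,790
1800,McEvedy & Jones,900
1800,Kremer,900
1800,Biraben,954
1800,Blaxter,954
1800,Clark,890
1800,UN 1999,980
1850,McEvedy & Jones,1200
1850,Kremer,1200
1850,Biraben,1241
1850,Blaxter,1241
1850,Clark,1190
1850,Haub,1265
1850,UN 1999,1260
1875,McEvedy & Jones,1325
1875,Kremer,1325
1900,McEvedy & Jones,1625
1900,Kremer,1625
1900,Biraben,1634
1900,Blaxter,1633
1900,Clark,1668
1900,Haub,1656
1900,UN 1999,1650
1920,Kremer,1813
1920,UN 1999,1860
1930,Kremer,1987
1930,UN 1999,2070
1940,Kremer,2213
1940,UN 1999,2300
1950,McEvedy & Jones,2500
1950,Kremer,2516
1950,Biraben,2530
1950,Blaxter,2513
1950,Haub,2516
1950,UN 1999,2520
1955,UN census,2752
1960,UN census,3020
1965,UN census,3336
1970,UN census,3698
1975,UN census,4079
1980,UN census,4448
1985,UN census,4851
1990,UN census,5292
1999,UN census,6000
2012,UN census,7000
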
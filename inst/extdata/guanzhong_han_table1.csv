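#population=Guanzhong Han
#gene_copies=1180
# Allele frequencies of 22 autosomal STR loci, Guanzhong Han population
# (590 unrelated individuals), transcribed from the published table.
# Transcription note: the published census is 247 alleles; one D6S477
# allele (frequency 0.0008, a single gene copy) was illegible in the
# source text and is restored here with the inferred label "20" -- its
# frequency is forced by the per-locus sum and the 247-allele census,
# but the repeat label itself could not be confirmed.
locus,allele,frequency
D10S1435,8,0.0203
D10S1435,9,0.0017
D10S1435,10,0.0322
D10S1435,11,0.1619
D10S1435,12,0.3695
D10S1435,13,0.2449
D10S1435,14,0.1517
D10S1435,15,0.0144
D10S1435,16,0.0034
D11S2368,15,0.0042
D11S2368,16,0.0364
D11S2368,17,0.1500
D11S2368,18,0.1034
D11S2368,19,0.1551
D11S2368,20,0.1636
D11S2368,21,0.2500
D11S2368,22,0.0915
D11S2368,23,0.0347
D11S2368,24,0.0085
D11S2368,25,0.0025
D12S391,15,0.0136
D12S391,16,0.0076
D12S391,17,0.0797
D12S391,18,0.2254
D12S391,18.3,0.0034
D12S391,19,0.2076
D12S391,20,0.1788
D12S391,21,0.1178
D12S391,22,0.0881
D12S391,23,0.0398
D12S391,24,0.0263
D12S391,25,0.0102
D12S391,26,0.0017
D13S325,15,0.0008
D13S325,16,0.0008
D13S325,17,0.0076
D13S325,18,0.0542
D13S325,19,0.2390
D13S325,20,0.3042
D13S325,21,0.1949
D13S325,22,0.1339
D13S325,23,0.0466
D13S325,24,0.0136
D13S325,25,0.0042
D14S608,5,0.0017
D14S608,6,0.0822
D14S608,7,0.2127
D14S608,8,0.0212
D14S608,9,0.0975
D14S608,10,0.2297
D14S608,11,0.2322
D14S608,12,0.0924
D14S608,13,0.0280
D14S608,14,0.0017
D14S608,15,0.0008
D15S659,8,0.0051
D15S659,9,0.0017
D15S659,10,0.0169
D15S659,11,0.1381
D15S659,12,0.2246
D15S659,13,0.1161
D15S659,14,0.0415
D15S659,15,0.1458
D15S659,16,0.1941
D15S659,17,0.0941
D15S659,18,0.0212
D15S659,19,0.0008
D16S539,8,0.0093
D16S539,9,0.2661
D16S539,10,0.1119
D16S539,11,0.2669
D16S539,12,0.2161
D16S539,13,0.1144
D16S539,14,0.0144
D16S539,15,0.0008
D17S1290,10,0.0347
D17S1290,11,0.0415
D17S1290,12,0.0169
D17S1290,13,0.0093
D17S1290,14,0.0220
D17S1290,15,0.2331
D17S1290,16,0.2992
D17S1290,17,0.1746
D17S1290,18,0.1025
D17S1290,18.3,0.0051
D17S1290,19,0.0398
D17S1290,20,0.0153
D17S1290,21,0.0042
D17S1290,22,0.0017
D18S535,9,0.2127
D18S535,10,0.0492
D18S535,11,0.0280
D18S535,12,0.0949
D18S535,13,0.2127
D18S535,14,0.2924
D18S535,15,0.1017
D18S535,16,0.0085
D19S253,7,0.1610
D19S253,8,0.0373
D19S253,9,0.0085
D19S253,10,0.0195
D19S253,11,0.1441
D19S253,12,0.3356
D19S253,13,0.1975
D19S253,14,0.0839
D19S253,15,0.0119
D19S253,16,0.0008
D1S1656,10,0.0008
D1S1656,11,0.0746
D1S1656,12,0.0398
D1S1656,13,0.0831
D1S1656,14,0.0856
D1S1656,15,0.3102
D1S1656,15.3,0.0008
D1S1656,16,0.2237
D1S1656,16.3,0.0025
D1S1656,17,0.0856
D1S1656,17.3,0.0415
D1S1656,18,0.0246
D1S1656,18.3,0.0127
D1S1656,19,0.0076
D1S1656,19.3,0.0042
D1S1656,20,0.0025
D20S470,6,0.0008
D20S470,9,0.0203
D20S470,10,0.1415
D20S470,11,0.0322
D20S470,12,0.0364
D20S470,13,0.1102
D20S470,14,0.1492
D20S470,15,0.1627
D20S470,16,0.1898
D20S470,16.2,0.0008
D20S470,17,0.1127
D20S470,18,0.0331
D20S470,19,0.0076
D20S470,20,0.0025
D21S1270,9,0.0025
D21S1270,9.3,0.0025
D21S1270,10,0.2941
D21S1270,11,0.0610
D21S1270,11.3,0.0008
D21S1270,12,0.0500
D21S1270,12.3,0.0415
D21S1270,13,0.1356
D21S1270,13.3,0.0347
D21S1270,14,0.2432
D21S1270,14.3,0.0059
D21S1270,15,0.1153
D21S1270,16,0.0127
D22-GATA198B05,14,0.0051
D22-GATA198B05,15,0.0186
D22-GATA198B05,16,0.0864
D22-GATA198B05,17,0.1492
D22-GATA198B05,18,0.0669
D22-GATA198B05,19,0.0958
D22-GATA198B05,20,0.1017
D22-GATA198B05,21,0.2856
D22-GATA198B05,22,0.1568
D22-GATA198B05,23,0.0297
D22-GATA198B05,24,0.0034
D22-GATA198B05,25,0.0008
D2S1338,16,0.0136
D2S1338,17,0.0653
D2S1338,18,0.1068
D2S1338,19,0.1737
D2S1338,20,0.1373
D2S1338,21,0.0314
D2S1338,22,0.0466
D2S1338,23,0.1551
D2S1338,24,0.1831
D2S1338,25,0.0644
D2S1338,26,0.0212
D2S1338,27,0.0008
D2S1338,28,0.0008
D3S3045,9,0.3390
D3S3045,10,0.0305
D3S3045,11,0.0373
D3S3045,12,0.1254
D3S3045,13,0.2305
D3S3045,14,0.1737
D3S3045,15,0.0627
D3S3045,16,0.0008
D4S2366,9,0.3331
D4S2366,10,0.0593
D4S2366,11,0.3398
D4S2366,12,0.1144
D4S2366,13,0.0678
D4S2366,14,0.0737
D4S2366,15,0.0119
D5S2500,9,0.0017
D5S2500,10,0.0169
D5S2500,11,0.2847
D5S2500,12,0.1449
D5S2500,13,0.0500
D5S2500,14,0.1076
D5S2500,15,0.2907
D5S2500,16,0.0847
D5S2500,17,0.0161
D5S2500,18,0.0025
D6S477,10,0.0085
D6S477,11,0.0034
D6S477,12,0.0593
D6S477,12.2,0.0008
D6S477,13,0.2203
D6S477,14,0.1975
D6S477,15,0.2915
D6S477,16,0.1771
D6S477,17,0.0288
D6S477,18,0.0093
D6S477,19,0.0025
D6S477,20,0.0008
D7S3048,15.3,0.0008
D7S3048,16,0.0008
D7S3048,17,0.0076
D7S3048,18,0.0949
D7S3048,19,0.0814
D7S3048,20,0.1881
D7S3048,21,0.1186
D7S3048,22,0.0805
D7S3048,23,0.1381
D7S3048,24,0.1729
D7S3048,25,0.0924
D7S3048,26,0.0212
D7S3048,27,0.0025
D8S1132,16,0.0161
D8S1132,17,0.0949
D8S1132,18,0.2229
D8S1132,19,0.1856
D8S1132,20,0.1297
D8S1132,21,0.1415
D8S1132,22,0.1076
D8S1132,23,0.0814
D8S1132,24,0.0136
D8S1132,25,0.0068
D9S925,11,0.0008
D9S925,12,0.0017
D9S925,13,0.0144
D9S925,14,0.1449
D9S925,15,0.2186
D9S925,15.3,0.0008
D9S925,16,0.3051
D9S925,16.3,0.0076
D9S925,17,0.2000
D9S925,17.3,0.0068
D9S925,18,0.0932
D9S925,19,0.0059
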
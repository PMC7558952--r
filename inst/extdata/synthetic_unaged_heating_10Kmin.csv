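time_s,temperature_K,cp_J_per_gK
783,310.5,1.2
795,312.5,1.2
807,314.5,1.2
819,316.5,1.2
831,318.5,1.2
843,320.5,1.2
855,322.5,1.2
867,324.5,1.2
879,326.5,1.2
891,328.5,1.19932338037782
903,330.5,1.19947566240102
915,332.5,1.19970987245559
927,334.5,1.19960261131304
939,336.5,1.19975184834141
951,338.5,1.19983523116673
963,340.5,1.19987390831368
975,342.5,1.1999469458397
987,344.5,1.20009233424473
999,346.5,1.20035749921821
1011,348.5,1.200739236769
1023,350.5,1.20136649787502
1035,352.5,1.20231724184638
1047,354.5,1.20375620782818
1059,356.5,1.20591377387311
1071,358.5,1.20909724957259
1083,360.5,1.21372913735321
1095,362.5,1.22038233819406
1107,364.5,1.2298235579946
1119,366.5,1.24307800716557
1131,368.5,1.26151102239647
1143,370.5,1.28693977678051
1155,372.5,1.32176249401903
1167,374.5,1.36906549141849
1179,376.5,1.43245688627107
1191,378.5,1.5148702748498
1203,380.5,1.61428045211355
1215,382.5,1.71324304239294
1227,384.5,1.7699195482047
1239,386.5,1.75343732191259
1251,388.5,1.70595700206705
1263,390.5,1.67912929667786
1275,392.5,1.67150092295929
1287,394.5,1.6701371513112
1299,396.5,1.67000457541385
1311,398.5,1.67000003208371
1323,400.5,1.67000000002335
1335,402.5,1.67
1347,404.5,1.67
1359,406.5,1.67
1371,408.5,1.67
1383,410.5,1.67
1395,412.5,1.67
1407,414.5,1.67
1419,416.5,1.67
1431,418.5,1.67
1443,420.5,1.67
1455,422.5,1.67
1467,424.5,1.67
1479,426.5,1.67
1491,428.5,1.67
1503,430.5,1.67
1515,432.5,1.67
1527,434.5,1.67
1539,436.5,1.67
1551,438.5,1.67
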
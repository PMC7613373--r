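center_nm,fwhm_nm
408,12
420,12
432,12
444,12
456,12
468,12
471,8
477.319,8
483.638,8
489.957,8
496.275,8
502.594,8
508.913,8
515.232,8
521.551,8
527.87,8
534.188,8
540.507,8
546.826,8
553.145,8
559.464,8
565.783,8
572.101,8
578.42,8
584.739,8
591.058,8
597.377,8
603.696,8
610.014,8
616.333,8
622.652,8
628.971,8
635.29,8
641.609,8
647.928,8
654.246,8
660.565,8
666.884,8
673.203,8
679.522,8
685.841,8
692.159,8
698.478,8
704.797,8
711.116,8
717.435,8
723.754,8
730.072,8
736.391,8
742.71,8
749.029,8
755.348,8
761.667,8
767.986,8
774.304,8
780.623,8
786.942,8
793.261,8
799.58,8
805.899,8
812.217,8
818.536,8
824.855,8
831.174,8
837.493,8
843.812,8
850.13,8
856.449,8
862.768,8
869.087,8
875.406,8
881.725,8
888.043,8
894.362,8
900.681,8
907,8
913.319,8
919.638,8
925.957,8
932.275,8
938.594,8
944.913,8
951.232,8
957.551,8
963.87,8
970.188,8
976.507,8
982.826,8
989.145,8
995.464,8
1001.783,8
1008.101,8
1014.42,8
1020.739,8
1027.058,8
1033.377,8
1039.696,8
1046.014,8
1052.333,8
1058.652,8
1064.971,8
1071.29,8
1077.609,8
1083.928,8
1090.246,8
1096.565,8
1102.884,8
1109.203,8
1115.522,8
1121.841,8
1128.159,8
1134.478,8
1140.797,8
1147.116,8
1153.435,8
1159.754,8
1166.072,8
1172.391,8
1178.71,8
1185.029,8
1191.348,8
1197.667,8
1203.986,8
1210.304,8
1216.623,8
1222.942,8
1229.261,8
1235.58,8
1241.899,8
1248.217,8
1254.536,8
1260.855,8
1267.174,8
1273.493,8
1279.812,8
1286.13,8
1292.449,8
1298.768,8
1305.087,8
1311.406,8
1317.725,8
1324.043,8
1330.362,8
1336.681,8
1343,8
1351,30
1381.4,30
1411.8,30
1442.2,30
1472.6,30
1503,30
1513,8
1519.364,8
1525.727,8
1532.091,8
1538.455,8
1544.818,8
1551.182,8
1557.545,8
1563.909,8
1570.273,8
1576.636,8
1583,8
1589.364,8
1595.727,8
1602.091,8
1608.455,8
1614.818,8
1621.182,8
1627.545,8
1633.909,8
1640.273,8
1646.636,8
1653,8
1659.364,8
1665.727,8
1672.091,8
1678.455,8
1684.818,8
1691.182,8
1697.545,8
1703.909,8
1710.273,8
1716.636,8
1723,8
1729.364,8
1735.727,8
1742.091,8
1748.455,8
1754.818,8
1761.182,8
1767.545,8
1773.909,8
1780.273,8
1786.636,8
1793,8
1803,30
1835,30
1867,30
1899,30
1931,30
1963,30
1995,30
2003,8
2009.182,8
2015.364,8
2021.545,8
2027.727,8
2033.909,8
2040.091,8
2046.273,8
2052.455,8
2058.636,8
2064.818,8
2071,8
2077.182,8
2083.364,8
2089.545,8
2095.727,8
2101.909,8
2108.091,8
2114.273,8
2120.455,8
2126.636,8
2132.818,8
2139,8
2151,28
2179.667,28
2208.333,28
2237,28
2265.667,28
2294.333,28
2323,28
2351.667,28
2380.333,28
2409,28
2437.667,28
2466.333,28
2495,28
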
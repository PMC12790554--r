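view	bit_name
list_1	Avalon_FP_1309
list_1	Avalon_FP_93
list_1	Avalon_FP_599
list_1	Avalon_FP_1436
list_1	Avalon_FP_1250
list_1	Avalon_FP_1969
list_1	Avalon_FP_487
list_1	Avalon_FP_1119
list_1	Avalon_FP_492
list_1	Avalon_FP_2013
list_1	Avalon_FP_12
list_1	Avalon_FP_932
list_1	Avalon_FP_231
list_1	Avalon_FP_2000
list_1	Avalon_FP_451
list_1	Avalon_FP_1122
list_1	Avalon_FP_422
list_1	Avalon_FP_1581
list_1	Avalon_FP_1548
list_1	Avalon_FP_1499
list_1	Avalon_FP_1236
list_1	Avalon_FP_1237
list_1	Avalon_FP_1498
list_1	Avalon_FP_2024
list_1	Avalon_FP_1157
list_1	Avalon_FP_297
list_1	Avalon_FP_443
list_1	Avalon_FP_399
list_1	Avalon_FP_1794
list_1	Avalon_FP_712
list_1	Avalon_FP_1414
list_1	Avalon_FP_339
list_1	Avalon_FP_1292
list_1	Avalon_FP_1570
list_1	Avalon_FP_1996
list_1	Avalon_FP_762
list_1	Avalon_FP_101
list_1	Avalon_FP_255
list_1	Avalon_FP_178
list_1	Avalon_FP_1040
list_2	Avalon_FP_1924
list_2	Avalon_FP_604
list_2	Avalon_FP_117
list_2	Avalon_FP_339
list_2	Avalon_FP_1838
list_2	Avalon_FP_384
list_2	Avalon_FP_1585
list_2	Avalon_FP_1280
list_2	Avalon_FP_1557
list_2	Avalon_FP_552
list_2	Avalon_FP_1097
list_2	Avalon_FP_1530
list_2	Avalon_FP_1967
list_2	Avalon_FP_159
list_2	Avalon_FP_1696
list_2	Avalon_FP_1119
list_2	Avalon_FP_1662
list_2	Avalon_FP_1689
list_2	Avalon_FP_152
list_2	Avalon_FP_816
list_2	Avalon_FP_200
list_2	Avalon_FP_1454
list_2	Avalon_FP_1713
list_2	Avalon_FP_361
list_2	Avalon_FP_1237
list_2	Avalon_FP_1202
list_2	Avalon_FP_879
list_2	Avalon_FP_1352
list_2	Avalon_FP_579
list_2	Avalon_FP_122
list_2	Avalon_FP_846
list_2	Avalon_FP_595
list_2	Avalon_FP_2020
list_2	Avalon_FP_955
list_2	Avalon_FP_1645
list_2	Avalon_FP_1285
list_2	Avalon_FP_2000
list_2	Avalon_FP_1669
list_2	Avalon_FP_1250
list_2	Avalon_FP_1684
list_2	Avalon_FP_834
list_2	Avalon_FP_790
list_2	Avalon_FP_1073
list_2	Avalon_FP_327
list_2	Avalon_FP_568
list_2	Avalon_FP_661
list_2	Avalon_FP_209
list_2	Avalon_FP_1861
list_2	Avalon_FP_985
list_2	Avalon_FP_1157
list_2	Avalon_FP_1136
list_2	Avalon_FP_1232
list_2	Avalon_FP_1850
list_2	Avalon_FP_1211
list_2	Avalon_FP_521
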
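patient,administered_MBq,estimated_MBq
Pat_1,555,480
Pat_2,570,652
Pat_3,759,967
Pat_4,781,788
Pat_5,966,1251
Pat_6,999,1009
Pat_7,1203,1202
Pat_8,1236,1221
Pat_9,1262,1288
Pat_10,1436,1350
Pat_11,1517,1572
Pat_12,2072,2188
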
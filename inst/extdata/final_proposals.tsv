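dataset	cluster	members
L	1	Others
L	2	33,54,79,108,112,123,144,146,147,160,178,208,223,333,397,472,551,564
L	3	121,379,381
L	4	454
L	5	197,249
L	6	92,646,650
L	7	35,120,315,427
L	8	309
L	9	151,319,418,546
L	10	548
LE	1	383,517,534,545,596,631,666
LE	2	120
LE	3	249,331,375,548
LE	4	198
LE	5	411
LE	6	79
LE	7	76,240
LE	8	Others
LE	9	121,379,381
LE	10	462,680,707
LE	11	90,128,166,276,401,434,438,489,491,537
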
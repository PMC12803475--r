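dataset	pattern	runs	cluster	members
L	1	Single (e, se, ci, mi), Complete (ch)	1	121,379,381
L	2	Single (ch), Average (ch), Centroid (ch)	1	92,646,650
L	2	Single (ch), Average (ch), Centroid (ch)	2	548
L	2	Single (ch), Average (ch), Centroid (ch)	3	121,379,381
L	2	Single (ch), Average (ch), Centroid (ch)	4	309
L	2	Single (ch), Average (ch), Centroid (ch)	5	33,54,79,108,112,123,144,146,147,160,178,208,223,333,397,472,551,564
L	2	Single (ch), Average (ch), Centroid (ch)	6	454
L	2	Single (ch), Average (ch), Centroid (ch)	7	35,120,315,427
L	3	Single (sp), Complete (sp), Average (sp), Centroid (sp)	1	197,249
L	4	Complete, Average, Centroid (e, se, ci, mi)	1	92,646,650
L	4	Complete, Average, Centroid (e, se, ci, mi)	2	548
L	4	Complete, Average, Centroid (e, se, ci, mi)	3	121,379,381
L	4	Complete, Average, Centroid (e, se, ci, mi)	4	309
L	4	Complete, Average, Centroid (e, se, ci, mi)	5	33,54,79,108,112,123,144,146,147,160,178,208,223,333,397,472,551,564
L	4	Complete, Average, Centroid (e, se, ci, mi)	6	454
L	4	Complete, Average, Centroid (e, se, ci, mi)	7	35,120,315,427
L	4	Complete, Average, Centroid (e, se, ci, mi)	8	151,319,418,546
LE	5	Single (e, se, ci, mi), Average (e, se, ci, mi), Centroid (e, se, ci, mi)	1	120
LE	6	Single (ch)	1	462,680,707
LE	6	Single (ch)	2	76,240
LE	6	Single (ch)	3	121,379,381
LE	6	Single (ch)	4	383,517,534,545,596,631,666
LE	6	Single (ch)	5	90,128,166,276,401,434,438,489,491,537
LE	7	Complete (ci)	1	120,331
LE	8	Average (ch)	1	411
LE	8	Average (ch)	2	198
LE	9	Average (sp), Centroid (sp)	1	79
LE	10	Centroid (ch)	1	375
LE	10	Centroid (ch)	2	249
LE	11	Single (sp)	1	249
LE	11	Single (sp)	2	548
LE	11	Single (sp)	3	120
LE	11	Single (sp)	4	331
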
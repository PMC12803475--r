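dataset	directive	members
LE	1	120
LE	2	249,331,375,548
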
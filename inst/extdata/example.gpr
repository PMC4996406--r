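ATF	1.0
3	5
"Type=GenePix Results 3"
"Scanner=synthetic example (not from a real instrument)"
"PixelSize=10"
Block	Name	ID	F532 Median	B532 Median
1	pepA	id1	250	90
1	pepA	id2	240	95
1	pepB	id3	80	110
1	pepB	id4	85	105
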
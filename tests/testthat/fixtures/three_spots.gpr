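ATF	1.0
2	9
"Type=GenePix Results 3"
"SampleID=fixture_sample"
"Block"	"Column"	"Row"	"Name"	"ID"	"F532 Median"	"B532 Median"	"F635 Median"	"B635 Median"
1	1	1	pep_a	pep_a	500	100	800	120
1	2	1	pep_b	pep_b	100	100	50	100
1	3	1	pep_c	pep_c	1250.5	90.25	64	80
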
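multiplicity	observed_cumulative	expected_cumulative
2	646	1065
3	202	376
4	62	87
5	16	14
6	6	1
7	3	1
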
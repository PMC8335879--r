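pattern	n
	1268
ldh	187
ldh;crp	107
crp	74
iss	46
iss;ldh;crp	30
iss;ldh	28
who_ps	27
who_ps;ldh	20
who_ps;ldh;crp	16
who_ps;iss;ldh;crp	13
iss;crp	9
who_ps;iss;ldh	9
who_ps;crp	7
lw_ratio;who_ps;iss;ldh;crp	5
who_ps;iss	4
lw_ratio	1
lw_ratio;ldh;crp	1
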
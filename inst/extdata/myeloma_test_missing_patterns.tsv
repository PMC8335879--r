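pattern	n
	361
ldh	157
ldh;crp	140
crp	91
iss;ldh	42
iss;ldh;crp	33
iss	10
iss;crp	7
lw_ratio;ldh	2
who_ps;ldh;crp	2
lw_ratio;crp	1
lw_ratio;iss	1
who_ps;iss;ldh;crp	1
who_ps;crp	1
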
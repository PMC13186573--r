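set	q1	q3	p90	extreme
methods	1.40	2.40	3.45	5.42
results	1.40	2.40	3.39	5.42
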
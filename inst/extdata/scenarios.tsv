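# Default scenario grid: fractional discount or 'free' (50 g/day free
# distribution), per highest eligible wealth decile.
eligibility	intervention
2	0.2
2	0.5
2	0.8
2	free
4	0.2
4	0.5
4	0.8
4	free
6	0.2
6	0.5
6	0.8
6	free
8	0.2
8	0.5
8	0.8
8	free
10	0.2
10	0.5
10	0.8
10	free
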
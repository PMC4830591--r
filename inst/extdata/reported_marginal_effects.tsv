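# Published per-decile marginal effects (change in weekly grams bought per
# 1 INR per 10 g price increase) from the 2013 market-survey estimates.
model	decile	mfx
current	1	-26.44
current	2	-25.12
current	3	-26.33
current	4	-24.88
current	5	-27.31
current	6	-25.62
current	7	-20.82
current	8	-19.35
current	9	-18.84
current	10	-17.29
potential	1	-33.44
potential	2	-31.88
potential	3	-30.32
potential	4	-28.77
potential	5	-27.21
potential	6	-25.65
potential	7	-24.09
potential	8	-22.54
potential	9	-20.98
potential	10	-19.42
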
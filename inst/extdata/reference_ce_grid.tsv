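# Published cost-effectiveness components per subsidy scenario (intervention
# cost, production losses averted, DALYs averted), shipped for ratio-algebra
# reproduction checks.  eligibility = highest wealth decile eligible.
eligibility	intervention	cost_musd	losses_averted_musd	dalys_averted
2	20% discount	7.7	21.7	8462
2	50% discount	27.7	54.6	20759
2	80% discount	58	87.7	32587
2	50g/d for free	127.7	249.4	83604
4	20% discount	19	40.4	14690
4	50% discount	63.8	101.3	36033
4	80% discount	128.1	162.7	56558
4	50g/d for free	249.1	471.1	147680
6	20% discount	34.9	56.6	19468
6	50% discount	110.3	142	47765
6	80% discount	213.4	227.7	74997
6	50g/d for free	363.2	669.6	199341
8	20% discount	49.4	68.5	22631
8	50% discount	151.9	171.7	55554
8	80% discount	288.4	275.1	87267
8	50g/d for free	465	836.3	239314
10	20% discount	61.3	77.2	24778
10	50% discount	185.6	193.3	60840
10	80% discount	348.9	309.6	95599
10	50g/d for free	550.3	964.6	268301
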
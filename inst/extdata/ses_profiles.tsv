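# SES profiles of the 2013 birth cohort in Indian cities over 500,000 inhabitants.
# Columns: wealth decile (1 = poorest), cohort share, yearly mortality per 1000
# children, anemia prevalence by severity (before attribution to iron deficiency),
# IDA prevalence by severity (after 60% attribution), buyer-class shares, and
# current buyers' baseline weekly quantity (g) and price (INR per 10 g).
# Per-decile severity prevalences follow a documented gradient constrained to the
# published aggregates; regenerate with fpicce::default_ses_profiles().
decile	cohort_share	annual_mortality	anemia_mild	anemia_moderate	anemia_severe	prev_mild	prev_moderate	prev_severe	share_current	share_potential	share_non	baseline_qty	baseline_price
1	0.1461461461	7	0.2002669336	0.5942971888	0.05903614458	0.1201601602	0.3565783133	0.03542168675	0.106	0.659	0.235	442	5.16
2	0.1131131131	7	0.2036002669	0.574311017	0.05705076328	0.1221601602	0.3445866102	0.03423045797	0.155	0.614	0.231	442	5.16
3	0.1101101101	4.6	0.2069336003	0.5530282245	0.0549365786	0.1241601602	0.3318169347	0.03296194716	0.187	0.63	0.183	478	5.1
4	0.1081081081	4.6	0.2102669336	0.5304488114	0.05269359054	0.1261601602	0.3182692868	0.03161615432	0.28	0.553	0.167	478	5.1
5	0.1081081081	3.1	0.2136002669	0.5065727776	0.0503217991	0.1281601602	0.3039436665	0.03019307946	0.307	0.499	0.194	564	5.32
6	0.0950950951	3.1	0.2169336003	0.4814001231	0.04782120428	0.1301601602	0.2888400738	0.02869272257	0.311	0.505	0.184	564	5.32
7	0.09109109109	2.4	0.2202669336	0.4549308479	0.04519180608	0.1321601602	0.2729585087	0.02711508365	0.345	0.471	0.184	498	5.46
8	0.08608608609	2.4	0.2236002669	0.427164952	0.0424336045	0.1341601602	0.2562989712	0.0254601627	0.38	0.406	0.214	498	5.46
9	0.07407407407	2.5	0.2269336003	0.3981024354	0.03954659955	0.1361601602	0.2388614613	0.02372795973	0.351	0.477	0.172	552	5.69
10	0.06806806807	2.5	0.2302669336	0.3677432982	0.03653079121	0.1381601602	0.2206459789	0.02191847473	0.288	0.481	0.231	552	5.69
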
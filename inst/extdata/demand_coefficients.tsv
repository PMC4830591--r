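# First-difference demand estimates from the 2013 twelve-city market survey.
# current: constant-elasticity (log-log) model for current buyers;
# potential: level model for potential buyers.  n_obs = households.
model	form	beta0	beta1	se_beta0	se_beta1	n_obs
current	log	-0.328	0.016	0.059	0.01	1177
potential	level	-35	1.557	2.018	0.379	2402
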
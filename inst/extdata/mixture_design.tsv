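mix_id	chemical	concentration_uM
mix1	GABA	83.3
mix1	beta-alanine	83.3
mix1	2-aminopentane	83.3
mix1	benzylamine	83.3
mix1	butylamine	83.3
mix1	cystamine	83.3
mix2	dibutylamine	83.3
mix2	dimethylamine	83.3
mix2	N,N-dimethylcyclohexylamine	83.3
mix2	ethylamine	83.3
mix2	ethyleneamine	83.3
mix2	ethanolamine	83.3
mix3	hexylamine	83.3
mix3	isoamylamine	83.3
mix3	isobutylamine	83.3
mix3	isopropylamine	83.3
mix3	indole	83.3
mix3	cadaverine	83.3
mix4	methylamine	83.3
mix4	N-methylindole	83.3
mix4	N-methylpyrrolidine	83.3
mix4	N-methylpiperidine	83.3
mix4	pyrrolidine	83.3
mix4	putrescine	83.3
mix5	hexanal	83.3
mix5	ethyl butyrate	83.3
mix5	tryptamine	83.3
mix5	histamine	83.3
mix5	2-phenylethylamine	83.3
mix5	trimethylamine	83.3
mix6	2-methylbutylamine	83.3
mix6	cysteamine	83.3
mix6	1-amino propan-2-ol	83.3
mix6	3-methylthiopropylamine	83.3
mix6	agmatine	83.3
mix7	tyramine	83.3
mix7	N,N-dimethylethanolamine	83.3
mix7	octopamine	83.3
mix7	N,N-dimethylglycine	83.3
mix7	5-hydroxyindole-3-acetic acid	83.3
mix7	3-methoxytyramine	83.3
mix8	5-methoxytryptamine	83.3
mix8	4-methoxy phenethylamine	83.3
mix8	N,N-dimethylphenethylamine	83.3
mix8	5-methoxy-N,N-dimethyltryptamine	83.3
mix8	N,N-dimethylaniline	83.3
mix8	N,N-dimethylisopropylamine	83.3
mix9	1-dimethylamino propanol	83.3
mix9	2-dimethylaminoethanethiol	83.3
mix9	1-(2-aminoethyl)-pyrrolidine	83.3
mix10	1,7-diaminoheptane	83.3
mix10	1,8-diaminooctane	83.3
mix10	1,6-diaminohexane	83.3
mix10	1,10-diaminodecane	83.3
mix10	1,3-diaminopropane	83.3
mix11	spermine	83.3
mix11	spermidine	83.3
mix11	dopamine	83.3
mix11	serotonin	83.3
mix11	adenine	83.3
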
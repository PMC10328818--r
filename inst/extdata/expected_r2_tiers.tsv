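variable	tier	timepoint	r2_mean	r2_sd	n_mc	seed
delivery3	large	12m	0.0533063332524545	0.00948362075307919	5	424243
defecation_freq	medium	12m	0.0166907035724178	0.00343281119913184	5	424243
breastfeeding	none	12m	0.00474844824846268	0.00171315093800217	5	424243
parity	small	12m	0.0100765268271997	0.00418846486684166	5	424243
delivery3	large	3w	0.0821805711756871	0.0118725922522733	5	424243
defecation_freq	medium	3w	0.0164404180064778	0.00529971787570685	5	424243
breastfeeding	none	3w	0.00491325219200908	0.0036835711551447	5	424243
parity	small	3w	0.00884065140128574	0.00489819168216434	5	424243
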
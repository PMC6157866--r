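variant_id	chgvs	label
APCfs	c.735_736insT	chr5:112136981-112136982insT
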
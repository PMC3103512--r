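line_id	term
line01	telencephalon
line01	diencephalon
line01	mesencephalon
line01	rhombencephalon
line01	olfactory_epithelium
line02	diencephalon
line02	thalamus
line03	mesencephalon
line03	optic_tectum
line03	olfactory_epithelium
line04	rhombencephalon
line04	spinal_cord
line04	hindbrain
line05	forebrain
line05	hypothalamus
line05	retina
line06	midbrain
line06	tegmentum
line07	cerebellum
line07	medulla_oblongata
line08	neural_tube
line08	trigeminal_ganglion
line08	lateral_line
line09	otic_vesicle
line09	diencephalon
line09	spinal_cord
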
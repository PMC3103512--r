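telencephalon
diencephalon
mesencephalon
rhombencephalon
spinal_cord
forebrain
midbrain
hindbrain
cerebellum
optic_tectum
retina
neural_tube
neural_crest
olfactory_epithelium
otic_vesicle
cranial_ganglion
trigeminal_ganglion
lateral_line
hypothalamus
thalamus
epiphysis
habenula
tegmentum
torus_semicircularis
medulla_oblongata
floor_plate
roof_plate
motor_neuron
interneuron
sensory_neuron
peripheral_nervous_system
sympathetic_ganglion
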
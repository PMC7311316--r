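# L-arginine biosynthesis from glutamate, with the two route variants
# that differ in the acyl group protecting the intermediates: acetylated
# (argA starts it) or succinylated (argA2 starts it). The shared kinase
# (argB) and the common tail (argC here, standing in for the rest of the
# route) are used by both variants.
pathway arg
step argA: N-acetylglutamate synthase :: EC:2.3.1.1
step argA2: N-succinylglutamate synthase :: term:argA2
step argB: N-acylglutamate kinase :: EC:2.7.2.8
step argC: N-acylglutamyl-phosphate reductase :: EC:1.2.1.38
rule acet = argA argB
rule succ = argA2 argB
rule all = acet argC | succ argC
# the succinylated route starts from intermediates whose synthesis needs
# an intact phosphorylated serine route upstream in this toy set
require succ: ser/serA present
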
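# L-methionine biosynthesis from homoserine. Sulfur is attached either by
# transsulfuration via cystathionine (metB then metC) or directly by
# O-succinylhomoserine sulfhydrylase (metZ); both routes end with a
# methionine synthase (metE).
pathway met
step metA: homoserine O-succinyltransferase :: EC:2.3.1.46
step metB: cystathionine gamma-synthase :: EC:2.5.1.48
step metC: cystathionine beta-lyase :: EC:4.4.1.13, term:metC
step metZ: O-succinylhomoserine sulfhydrylase :: EC:2.5.1.-
# O-acetylhomoserine sulfhydrylases are hard to tell apart from metZ;
# hits to them should not count as evidence of another function
ignore metZ: EC:2.5.1.49
step metE: cobalamin-independent methionine synthase :: EC:2.1.1.14
rule trans = metB metC | metZ
rule all = metA trans metE
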
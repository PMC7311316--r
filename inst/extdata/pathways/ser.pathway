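# L-serine biosynthesis from 3-phosphoglycerate (phosphorylated route)
pathway ser
step serA: 3-phosphoglycerate dehydrogenase :: EC:1.1.1.95
step serC: phosphoserine aminotransferase :: EC:2.6.1.52, term:serC
step serB: phosphoserine phosphatase :: EC:3.1.3.3
rule all = serA serC serB
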
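trait	n_sites
Resistance to powdery mildew	129
Resistance to root knot nematodes	6
Resistance to cucumber mosaic virus	140
Resistance to tobacco mosaic virus	3
Resistance to pepper blight	27
Resistance to aphids	1
Resistance to anthrax disease	1
Resistance to Potato Y Virus	4
Resistance to bacterial wilt	30
Resistance to thrips	4
Chlorophyll	73
Inhibition alpha-glucosidase	4
Dry matter content	44
Capsaicin	17
Flavonoid	10
Purple fruit	48
Fruit flavor	23
VC content	7
Fruit color	16
Anthocyanin	2
Leaf surface fuzziness	6
Leaf margin	78
Leaf color	1
Fruit shoulder shape	6
Fruit surface luster	1
Pericarp thick	12
Fruit orientation	46
Fruit position	25
Fruit shape	44
Fruit weight	49
Number of ventricles	14
Single node with multi flower	177
Corolla color	55
Peduncle length	45
Anther color	78
The node position of flowers	167
GMS	5
Male sterile	2
Branch type	304
Main stem color	22
Plant architecture	124
Pigmented peppers	8
Stem hairiness	11
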
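qtl	contig	pos	gene_context	p_value	contribution
heli2.1	Chr02	90049878	Between Chr02g007170 and Chr02g007180	3.17e-12	0.12353
heli2.1	Chr02	90049913	Between Chr02g007170 and Chr02g007180	3.17e-12	0.12353
heli11.1	Chr11	3585223	Chr11g001780 exon	7.37e-08	0.07964
heli11.1	Chr11	4841180	Chr11g002450 exon	1.36e-09	0.09759
heli11.1	Chr11	11717741	Between Chr11g005030 and Chr11g005040	6.19e-10	0.10107
heli11.1	Chr11	11749401	Between Chr11g005040 and Chr11g005050	3.18e-08	0.08358
heli11.1	Chr11	13044490	Between Chr11g005370 and Chr11g005380	3.61e-07	0.07236
heli11.1	Chr11	15115808	Between Chr11g005900 and Chr11g005910	1.31e-06	0.06638
heli11.2	Chr11	183571838	Between Chr11g015600 and Chr11g015610	6.57e-07	0.0721
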
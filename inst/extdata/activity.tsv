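compound	target	ic50_uM	sem_uM	derived
5n	AChE	4.24	NA	no
5n	BChE	22.00	NA	no
6aa	BChE	3.97	NA	no
6aa	AChE	99.25	NA	yes
galantamine	BChE	8.80	NA	no
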
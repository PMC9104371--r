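model	dataset	predicted	negative	neutral	positive
mlp	students	negative	165	8	2
mlp	students	neutral	1	22	6
mlp	students	positive	6	2	13
mlp	staff	negative	70	3	5
mlp	staff	neutral	0	22	4
mlp	staff	positive	1	3	32
svm	students	negative	160	11	3
svm	students	neutral	8	18	9
svm	students	positive	4	3	9
svm	staff	negative	66	5	11
svm	staff	neutral	3	15	9
svm	staff	positive	2	8	21
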
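model	dataset	metric	value
mlp	students	WeightedAccuracy	92.49
mlp	staff	WeightedAccuracy	92.59
svm	students	WeightedAccuracy	88.42
svm	staff	WeightedAccuracy	82.55
mlp	students	WeightedPrecision	88.89
mlp	staff	WeightedPrecision	88.57
svm	students	WeightedPrecision	83.11
svm	staff	WeightedPrecision	72.86
mlp	students	WeightedRecall	88.64
mlp	staff	WeightedRecall	88.47
svm	students	WeightedRecall	82.86
svm	staff	WeightedRecall	71.77
mlp	students	WeightedF1	88.74
mlp	staff	WeightedF1	88.29
svm	students	WeightedF1	82.88
svm	staff	WeightedF1	71.75
mlp	students	Accuracy	88.88
mlp	staff	Accuracy	88.57
svm	students	Accuracy	83.11
svm	staff	Accuracy	72.85
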
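cancer_label	cancer_type	n_samples
GBM	Glioblastoma multiforme	582
OV	Ovarian cancer	582
BRCA	Breast cancer	534
COAD	Colon adenocarcinoma	162
LUSC	Lung squamous cell carcinoma	154
UCEC	Uterine corpus endometrial adenocarcinoma	54
READ	Rectal adenocarcinoma	70
KIRC	Kidney clear cell renal carcinoma	72
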
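model,augmented,accuracy,precision,sensitivity,specificity,f_score
LR,FALSE,0.8077,0.9091,0.7143,0.9167,0.8000
SMO,FALSE,0.8462,0.9167,0.7857,0.9167,0.8462
SMO,TRUE,0.8846,0.9231,0.8571,0.9167,0.8889
ResDen,FALSE,0.9231,0.9286,0.9286,0.9167,0.9286
ResDen,TRUE,0.9487,0.9524,0.9524,0.9444,0.9524
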
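condition,mask,algorithm_decision,n,pct_correct,fpr,tpr,d_prime,c
control,no_mask,NONE,49,0.77,0.14,0.69,1.56,0.29
no_mask,no_mask,DIFFERENT,51,0.79,0.16,0.75,1.66,0.15
no_mask,no_mask,SAME,51,0.81,0.21,0.82,1.74,-0.06
mask,mask,DIFFERENT,50,0.70,0.13,0.52,1.19,0.55
mask,mask,SAME,50,0.63,0.33,0.59,0.67,0.10
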
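condition,mask,algorithm_decision,n,pct_correct,fpr,tpr,d_prime,c
alg65,mask,DIFFERENT,162,0.68,0.24,0.59,0.94,0.24
alg65,mask,SAME,162,0.69,0.29,0.66,0.97,0.08
alg95,mask,DIFFERENT,172,0.70,0.21,0.61,1.09,0.27
alg95,mask,SAME,172,0.67,0.32,0.67,0.90,0.02
control,no_mask,NONE,163,0.78,0.17,0.72,1.54,0.18
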
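method,k,class,p_at_k
SE-CBIR,1,akiec,0.59
SE-CBIR,1,bcc,0.82
SE-CBIR,1,bkl,0.82
SE-CBIR,1,df,1.00
SE-CBIR,1,mel,0.81
SE-CBIR,1,nv,0.95
SE-CBIR,1,vasc,0.93
SE-CBIR,3,akiec,0.57
SE-CBIR,3,bcc,0.82
SE-CBIR,3,bkl,0.78
SE-CBIR,3,df,0.97
SE-CBIR,3,mel,0.72
SE-CBIR,3,nv,0.95
SE-CBIR,3,vasc,0.88
SE-CBIR,6,akiec,0.56
SE-CBIR,6,bcc,0.83
SE-CBIR,6,bkl,0.75
SE-CBIR,6,df,0.98
SE-CBIR,6,mel,0.69
SE-CBIR,6,nv,0.95
SE-CBIR,6,vasc,0.89
SE-CBIR,9,akiec,0.56
SE-CBIR,9,bcc,0.83
SE-CBIR,9,bkl,0.75
SE-CBIR,9,df,0.96
SE-CBIR,9,mel,0.69
SE-CBIR,9,nv,0.95
SE-CBIR,9,vasc,0.90
CBIR,1,akiec,0.69
CBIR,1,bcc,0.75
CBIR,1,bkl,0.80
CBIR,1,df,0.55
CBIR,1,mel,0.67
CBIR,1,nv,0.95
CBIR,1,vasc,1.00
CBIR,3,akiec,0.59
CBIR,3,bcc,0.67
CBIR,3,bkl,0.63
CBIR,3,df,0.64
CBIR,3,mel,0.54
CBIR,3,nv,0.92
CBIR,3,vasc,0.83
CBIR,6,akiec,0.52
CBIR,6,bcc,0.66
CBIR,6,bkl,0.57
CBIR,6,df,0.58
CBIR,6,mel,0.49
CBIR,6,nv,0.92
CBIR,6,vasc,0.79
CBIR,9,akiec,0.46
CBIR,9,bcc,0.65
CBIR,9,bkl,0.55
CBIR,9,df,0.60
CBIR,9,mel,0.47
CBIR,9,nv,0.92
CBIR,9,vasc,0.75
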
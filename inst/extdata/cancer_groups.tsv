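cancer_type	group
GC	digestive
EC	digestive
CC	digestive
RC	digestive
BLCA	urinary
PCA	urinary
LC	lung
BC	breast
KS	other
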
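# External-validation Q2 of the best 7-variable fuzzy (Choquet-integral)
# and non-fuzzy descriptor models on eight benchmark QSAR datasets,
# transcribed from the published comparison.
dataset,q2_ext_fuzzy,q2_ext_nonfuzzy
ACE,0.6103,0.5629
ACHE,0.5231,0.3887
BZR,0.5400,0.5222
COX2,0.3558,0.3387
DHFR,0.4638,0.4390
GPB,0.6447,0.6442
THER,0.4569,0.4080
THR,0.4072,0.3600
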
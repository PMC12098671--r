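# reference tablet-assay summaries: the synchronous-derivative method
# ("proposed") versus the previously reported technique ("reported")
analyte,method,n,mean_recovery,rsd,variance
ATO,proposed,5,99.83,1.128,1.269
ATO,reported,5,100.48,1.314,1.743
ASP,proposed,5,99.8,0.3,0.09
ASP,reported,5,99.85,0.48,0.23
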
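# reference laboratory-mixture selectivity study for the co-formulated
# ATO/ASP assay (fixed 1:3.75 ratio series); concentrations in ug/mL
analyte,added,found,percent_recovery
ATO,0.5,0.504,100.77
ATO,1,0.981,98.12
ATO,1.5,1.499,99.91
ATO,2,2.027,101.35
ATO,2.5,2.521,100.83
ASP,1.875,1.857,99.05
ASP,3.75,3.744,99.83
ASP,5.625,5.552,98.72
ASP,7.5,7.451,99.34
ASP,9.375,9.508,101.42
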
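# reference standard-addition (spike recovery) study for the ATO/ASP
# tablet assay; concentrations in ug/mL
analyte,base_taken,base_found,added,pure_found,percent_recovery
ATO,20,19.92,0.5,0.496,99.18
ATO,20,19.92,1,0.986,98.57
ATO,20,19.92,1.5,1.514,100.94
ATO,20,19.92,2,1.974,98.72
ASP,75,75.21,1.875,1.899,101.28
ASP,75,75.21,3.75,3.728,99.40
ASP,75,75.21,5.625,5.662,100.65
ASP,75,75.21,7.5,7.637,101.83
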
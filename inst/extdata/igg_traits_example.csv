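trait,formula
IgG1_fucosylation,IgGI1H3N4F1 + IgGI1H4N4F1 + IgGI1H5N4F1 + IgGI1H3N5F1 + IgGI1H4N5F1 + IgGI1H4N4F1S1 + IgGI1H5N4F1S1
IgG1_bisection,IgGI1H3N5F1 + IgGI1H4N5F1
IgG1_agalactosylation,IgGI1H3N4 + IgGI1H3N4F1 + IgGI1H3N5F1
IgG1_galactosylation_per_antenna,0.5 * IgGI1H4N4 + 0.5 * IgGI1H4N4F1 + 0.5 * IgGI1H4N5F1 + 0.5 * IgGI1H4N4F1S1 + IgGI1H5N4 + IgGI1H5N4F1 + IgGI1H5N4F1S1
IgG1_sialylation_per_antenna,0.5 * IgGI1H4N4F1S1 + 0.5 * IgGI1H5N4F1S1
IgG1_fucosylation_of_digalactosylated,IgGI1H5N4F1 + IgGI1H5N4F1S1 / IgGI1H5N4 + IgGI1H5N4F1 + IgGI1H5N4F1S1
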
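# rescale_rule: to_age_units
analyte,weight,transform,scaling
m001,0.21,log,cohort_z
m002,-0.15,log,cohort_z
m003,0.12,log,cohort_z
m004,-0.27,log,cohort_z
m005,0.08,log,cohort_z
m006,0.19,log,cohort_z
m007,-0.11,log,cohort_z
m008,0.05,log,cohort_z
m009,-0.22,log,cohort_z
m010,0.17,log,cohort_z
m011,0.09,log,cohort_z
m012,-0.06,log,cohort_z
m013,0.14,log,cohort_z
m014,-0.18,log,cohort_z
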
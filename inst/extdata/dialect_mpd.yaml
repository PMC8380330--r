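# Column-header dialect for MPD-style animal and group-summary tables.
# Keys are canonical field names; values are the header used in the file.
project_id: projsym
parameter_key: parameter
strain: strain
strain_class: strain_class
sex: sex
age_weeks: age_weeks
treated: treated
value: value
n: n
mean: mean
sd: sd
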
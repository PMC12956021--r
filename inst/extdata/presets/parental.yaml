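# Parental-population replicate measurements: population-level noise
# only (no clonal heterogeneity), replicate CV 0.11 from n = 11 repeats.
name: parental
kind: parental
version: 1
mean_survival: 0.9
noise_cv: 0.11
n_replicates: 11
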
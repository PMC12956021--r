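# Heritable-continuum generator calibrated to the OV90 clone cohort:
# latent suspension growth rate Normal(-0.004, 0.012) per hour (cohort
# mean and SD of effective growth rates), memoryless across passages
# (rho = 0, matching the absence of inter-passage correlation), and a
# 3% multiplicative measurement CV, giving a total interclonal survival
# CV of about 0.30 at the 24 h assay.
name: ov90-clones
kind: continuum
version: 1
mu_g: -0.004
sigma_g: 0.012
rho: 0.0
meas_cv: 0.03
n_clones: 60
passages: [P1, P3, P6]
n_plated: 250000
duration_hours: 24
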
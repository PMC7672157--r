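# Template for a semi-synthetic study: real genotypes, simulated
# phenotypes. Requires user-supplied genotype files (PLINK prefix);
# never exercised by the shipped tests. Point `geno` at a QC'd cohort,
# then simulate phenotypes on its empirically standardized matrix with
# sim_polygenic_study()-style parameters and run the estimators via the
# package API; see the methods vignette. This file records the
# parameter levels of the full design.
scenario: recovery_grid
geno: /path/to/plink/prefix   # user-supplied; not distributed
"n": 10000
h2: [0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9]
f_c: 0.1
replicates: 30
n_std: 1000
methods: [gcv_projection, gcv_two_set, kfold_cv, reml_oracle]
seed: 1
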
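# reduced biased-feedback run: 6 observers, all ten models, fast MCMC
experiment: exp2
n_subjects: 6
seed: 1
models: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
mcmc_profile: fast
validate: false
out_dir: dyaddm-exp2-small
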
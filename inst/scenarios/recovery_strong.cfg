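# Size-factor recovery under a strong differential-abundance signal,
# at a reduced replicate count.  Run with:
#   rsim benchmark --scenario recovery_strong.cfg --out results/
replicates = 5
methods = "rsim,tss,uq,med,tmm,gmpr,oracle"
analyses = "recovery,misclass"
d = 200
n = 100
prop_da = 0.1
signal = 4
latent = binary
eta = 0.05
gamma = 0.8
n_resamples = 100
seed = 1
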
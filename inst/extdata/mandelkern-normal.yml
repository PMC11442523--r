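# Bounded normal mean, beta-elicited prior
prior: {family: beta, l0: 0, u0: 10, l1: 0.5, u1: 9.5, m0: 5, gamma: 0.99}
sigma0: 1
n: 10
mu_star: 4
delta: 0.5
n_mc: 1000000
reps: 100000
seed: 1
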
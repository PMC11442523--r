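# Bounded Poisson rate, gamma_rate-elicited prior
prior: {family: gamma_rate, l1: 3.5, u1: 9.5, m0: 6.5, gamma: 0.99}
l0: 3
u0: 10
n: 100
lambda_star: 6.2
delta: 0.5
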
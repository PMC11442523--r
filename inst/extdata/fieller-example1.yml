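# Simulated ratio-of-means study: nx = ny = 10, sigma0 = 1, psi true = 2
data:
  xbar: 20.188
  ybar: 10.699
  nx: 10
  ny: 10
  sigma0: 1
priors:
  mu: {family: normal, m1: 10, m2: 25, gamma: 0.99}
  nu: {family: fieller_nu, m1: 10, m2: 25, r1: 1, r2: 3, psi0: 2, gamma: 0.99}
delta: 0.1
gamma: 0.95
reps: 100000
seed: 1
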
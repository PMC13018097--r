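# Stochastic-extinction ensemble: 2D, high burst size, halved clearance,
# initial infection spanning the whole tumour (R_v = R_u). The full-scale
# experiment uses 100 replicates to 1500 h at tau = 0.02, delta = 0.1;
# desk-scale runs use fewer replicates and a 500 h horizon (the extinction
# window closes by 200 h).

[model]
p = 1.87e-2
q = 4.17e-2
q_v = 8.33e-2        # half of the lower reference clearance
alpha = 3500
beta = 7.00e-4
D_v = 1.00e-2
K = 1e4
movement = undirected
dimension = 2

[numerics]
tau = 0.02
delta = 0.1
dx = 0.1
dt = 1e-3
L = 5

[initial]
R_u = 2.6
R_v = 2.6            # wide initial infection
V_0 = 7.1289e6       # (2.67e3)^2

[run]
horizon = 1500
seed = 1
replicates = 100
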
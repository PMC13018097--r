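# Infection wave-speed scan: minimal spreading speed against the clearance
# rate at fixed burst-to-clearance ratio alpha/q_v = 3500, for three viral
# diffusivities.

[model]
p = 1.87e-2
q = 4.17e-2
q_v = 1.00
alpha = 3500
beta = 7.00e-4
D_U = 1.88e-4
D_v = 1.00e-2
K = 1e3
movement = undirected
dimension = 1

[numerics]
tau = 0.02
delta = 0.1

[initial]
R_u = 2.6
R_v = 0.5
V_0 = 2.67e4

[run]
q_v_values = 0.001,0.00178,0.00316,0.00562,0.01,0.0178,0.0316,0.0562,0.1,0.178,0.316,0.562,1,1.78,3.16,5.62,10
D_v_values = 1e-3,1e-2,1e-1
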
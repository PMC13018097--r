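# Reference parameter set (1D, undirected movement, lower burst size /
# clearance pair).

[model]
p = 1.87e-2          # maximal duplication rate (1/h)
q = 4.17e-2          # lysis rate of infected cells (1/h)
q_v = 1.67e-1        # viral clearance rate (1/h)
alpha = 580          # burst size (virions per lysed cell)
beta = 7.00e-4       # infection rate (virions/(cells h), scaled by K)
D_U = 1.88e-4        # undirected cell diffusivity (mm^2/h)
D_P = 1.504e-3       # pressure-driven diffusivity, 8*D_U (mm^2/h)
D_v = 1.00e-2        # viral diffusivity (mm^2/h)
K = 1e3              # carrying capacity (cells/mm)
movement = undirected
dimension = 1

[numerics]
tau = 0.02           # ABM time step (h)
delta = 0.1          # ABM lattice spacing (mm)
dx = 0.1             # PDE grid spacing (mm)
dt = 1e-3            # PDE time step (h)
L = 10               # domain half-length (mm)

[initial]
R_u = 2.6            # uninfected plateau radius (mm)
R_v = 0.5            # viral plateau radius (mm)
R_i = 0
V_0 = 2.67e4         # viral plateau height (1D)

[run]
horizon = 500
seed = 1
replicates = 5
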
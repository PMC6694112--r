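# Example run configuration for the bnpfcs command-line tool.
# Units are fixed package-wide: micrometres, seconds, photons per second.
seed: 1
psf:
  variant: gaussian3d
  omega_xy_um: 0.3
  omega_z_um: 1.5
sim:
  D: 10.0           # um^2/s
  mu_mol: 50000.0   # photons/s at the PSF centre
  mu_back: 1000.0   # photons/s
  dt: 1.0e-4        # s
  K: 1000
  n_molecules: 5
  init_region: [0.3, 0.3, 1.5]
priors:
  N_model: 20
  A_q: 1.0
  B_q: 9.0
mcmc:
  n_iter: 3000
  n_components: 1
io:
  trace: trace.txt
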
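# Default protein-dsDNA simulation: a preformed droplet with a
# DNA-coated surface evolving into a hollow co-condensate.
grid:
  nx: 128
  ny: 128
params:
  psi_c: 0.85
  b1: 0.14
  coupling_mode: hydrophobic_only
ic:
  zeta_protein: 0.17
  zeta_dna: 0.05
  seed: 1
run:
  t_end: 600
  save_every: 50
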
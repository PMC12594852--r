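# Protein-RNA variant: the amphiphilic copolymer moves through both
# hydrophobic and hydrophilic regions and partitions to the surfaces.
grid:
  nx: 128
  ny: 128
params:
  coupling_mode: both
ic:
  zeta_protein: 0.17
  zeta_dna: 0.05
  seed: 1
run:
  t_end: 600
  save_every: 50
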
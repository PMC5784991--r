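# Example simulation configuration. Any sim_params() field can be overridden
# under `params` (rate tables merge entrywise over the defaults, keyed by
# pair class: intra_andrei, intra_fetida, interspecific, backcross,
# hybrid_hybrid); `seq_gen` overrides seq_gen_params(); `design` replaces the
# default three-arm pairing design.
seed: 1
params:
  h_a: 0.3
  h_f: 0.3
  fFA_F1_viability: 0
  hybrid_pair_fertility: 0
design:
  - {arm: Ea+Ea, gt1: aAA, gt2: aAA, n_pairs: 4, weeks: 2}
  - {arm: Ef+Ef, gt1: fFF, gt2: fFF, n_pairs: 4, weeks: 2}
  - {arm: Ea+Ef, gt1: aAA, gt2: fFF, n_pairs: 7, weeks: 2}
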
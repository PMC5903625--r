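# Bundled synthetic-study configuration: the four-diet (NPLF/NPHF/HPLF/HPHF)
# design with three NPLF mice in the metatranscriptome subset, planted
# 4-fold diet-responsive modules and elevated branched-chain acids under
# high protein. Depth is desk scale; raise for heavier simulations.
seed: 1
output_dir: mtxprof_out
alpha: 0.05
n_permutations: 999
alignment_format: tsv
synthetic:
  orfs_per_family: 320
  n_background: 116
  depth: 2.0e+5
  dispersion: 0.2
  fold_change: 4
  read_length: 100
  scfa_mice_per_group: 10
  replicates:
    NPLF: 3
    NPHF: 4
    HPLF: 4
    HPHF: 4
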
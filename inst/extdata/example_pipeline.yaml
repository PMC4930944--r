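# Example end-to-end configuration for run_pipeline(): simulates a small
# three-genome community with contrasted abundances, maps, bins and
# summarizes it. All randomness is controlled by `seed`.
community:
  n_genomes: 3
  genome_length_bp: 20000
  fragment_mean_bp: 6000
  fragment_min_bp: 2000
  n_markers: 107
  abundance_matrix:
    S1: [0.65, 0.25, 0.10]
    S2: [0.10, 0.25, 0.65]
alignments:
  depth_per_sample: 15
  read_bp: 100
  insert_bp: 300
filter:
  min_identity: 0.95
  min_aligned_fraction: 0.70
linkage:
  min_links: 2
bin:
  sample_x: S1
  sample_y: S2
  radius: 0.2
  min_members: 2
  min_length_bp: 1000
refine:
  rounds: 1
  auto_trim: false
seed: 19
out_dir: ebprbin_run
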
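# Annotated orthocascade pipeline configuration.

# Focal (query) species label; file names and simulated identifiers use it.
focal: shrew

# Reference species in cascade priority order (rank 1 first). Each focal
# transcript is assigned to the first species with a reciprocal best hit.
species_priority: [human, mouse, dog, ferret]

# Alignment hits above this e-value are ignored by best-hit selection.
evalue_cutoff: 1.0e-5

# Number of conservation partitions (deciles by default).
partitions: 10

# Enrichment options: minimum term overlap, and whether to use the EASE
# (one-success-removed) variant of the Fisher exact test.
min_count: 2
ease: false

# All outputs are written below this directory.
out_dir: orthocascade_out

# Single top-level seed; all stage randomness derives from it.
seed: 42

# Optional extra gene-set list files (one id per line) to test for
# enrichment alongside the conservation partitions.
gene_sets: []

# Presence of this block makes run-all generate a synthetic study first.
# Every key of sim_config() may appear here; omitted keys keep defaults.
simulate:
  n_genes: 200
  fragment_rate: 0.15
  dropout_rate: 0.15
  paralog_rate: 0.05
  noise_rate: 0.05
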
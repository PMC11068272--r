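# Example run configuration for `coalsky infer` / `mlest` / `compare`.
model: skyfish            # constant | skyline | bsp | ebsp | skyride |
                          # skygrid | gmrf | hsmrf | skyfish
mode: constant            # per-interval demographic function: constant | linear
data:
  newick: data/isochronous36.trees   # one Newick tree per line
  ages: data/isochronous36_ages.tsv  # two-column TSV: label, age
  # multilocus: true                 # treat multiple trees as loci
  # ref_log_density: refs.tsv        # sequential inference references
scheme:
  t_max: 500000           # modeled period (grid models and skyfish)
  n_intervals: 50         # equal-grid models (skygrid, gmrf, hsmrf)
  events_per_group: 5     # skyline/bsp coalescent-event grouping
hyper: {}                 # overrides, e.g. {zeta: 0.0195, alpha_eq: 0.5}
mcmc:
  iterations: 100000
  thinning: 10
  burn_in_fraction: 0.1
  n_replicates: 2
stepping_stone:           # used by mlest / compare
  n_stones: 128
  iterations_per_stone: 5000
models: [constant, bsp, skyfish]   # used by compare
seed: 1
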
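# Example pipeline configuration for run_config_from_yaml().
# Scaled for a quick demonstration run; production chains would use the
# mcmc_settings() defaults (burn-in 30000, 300000 draws, thin 2) and
# bootstrap_B: 500 with all six settings.
out_dir: run-example
seed: 1
n_lines: 200
n_markers: 800
n_families: 10
settings:
  - gs3
  - tabu1
alpha: 0.01
n_permutations: 450
bootstrap_B: 50
sem_variants:
  - GstarR
  - GRstar
mcmc_mtm:
  burn_in: 500
  n_iter: 2000
  thin: 2
mcmc_sem:
  burn_in: 500
  n_iter: 2000
  thin: 2
cv_enabled: false
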
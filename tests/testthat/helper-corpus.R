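# Shared fixtures, built once per test run and cached. Everything is
# generated in code from fixed seeds; no data files.

.fixtures <- new.env(parent = emptyenv())

# 20-configuration smoke corpus: mean of 5 stochastic runs each
small_corpus <- function() {
  if (is.null(.fixtures$small)) {
    configs <- sample_configs(20, seed = 501)
    curves <- lapply(configs, function(cf)
      mean_activation(cf, n_runs = 5, seed = 7000 + 5 * cf$config_id))
    .fixtures$small <- list(configs = configs, curves = curves,
                            samples = lapply(curves, sample_curve))
  }
  .fixtures$small
}

# one mid-range configuration and its 20-run mean curve
reference_curve <- function() {
  if (is.null(.fixtures$ref)) {
    cfg <- synapse_config(2000, 5000, 500, 15, 1.5, config_id = 1L)
    .fixtures$ref <- list(config = cfg,
                          curve = mean_activation(cfg, n_runs = 20, seed = 42))
  }
  .fixtures$ref
}

# rational 4/4 coefficient sets whose denominators have no roots in [0, 1]
rational_test_coefs <- function() {
  list(c(0.0, 6.0, -2.0, 1.0, 0.5, 0.05, 0.10, 0.30, 0.20),
       c(0.2, 4.0, 1.0, -1.0, 0.3, 0.08, 0.15, 0.25, 0.30),
       c(0.0, 8.0, -4.0, 2.0, 0.1, 0.06, 0.12, 0.35, 0.25))
}
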
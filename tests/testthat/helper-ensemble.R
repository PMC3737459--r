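# default-condition ensemble shared between acceptance checks: one synthetic
# study at the default design, features, and the 20-trial training protocol
default_ensemble <- function(seed = 101) {
  key <- paste0("ens", seed)
  if (is.null(shared_env[[key]])) {
    fm <- default_features(seed)
    shared_env[[key]] <- suppressWarnings(
      run_trials(fm, config = mlp_config(seed = seed))
    )
  }
  shared_env[[key]]
}
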
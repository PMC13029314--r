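# Shared helpers: reduced hyperparameter grids for quick fits, cached
# expensive computations, and small constructed datasets.

# Small but real grid for unit tests where the full 5 x 50 grid is overkill.
cfg_small <- function(retune = TRUE) {
  fitConfig(alpha_grid = c(0.1, 0.5, 0.9),
            lambda_grid = 10^seq(-2, 2, length.out = 8),
            retune_per_fold = retune)
}

# Single-point grid: tuning degenerates to that pair (fast sweeps).
cfg_single <- function(alpha = 0.5, lambda = 0.1) {
  fitConfig(alpha_grid = alpha, lambda_grid = lambda)
}

# Cache for computations shared across test files (full-grid fits are the
# expensive part; each is computed once per test run).
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

full_models <- function() {
  cached("full_models", fitAllMethods(evCompounds(), fitConfig()))
}

train17_models <- function() {
  cached("train17_models",
         fitAllMethods(splitPredefined(evCompounds())$train, fitConfig()))
}

loocv17 <- function() {
  cached("loocv17", loocvValidate(splitPredefined(evCompounds())$train,
                                  fitConfig()))
}

# A strongly separated noiseless synthetic dataset: one method dominates in
# one half of descriptor space, another in the other half.
separated_spec <- function(n = 14, noise_sd = 0, seed = 7L) {
  B <- matrix(0, 5, 7)
  B[1, 1] <- 20   # passive rises steeply with logp
  B[3, 1] <- -20  # saponin falls with logp
  generatorSpec(
    n_compounds = n, coefficients = B,
    intercepts = c(50, 10, 50, 15, 15),
    noise_sd = noise_sd, seed = seed
  )
}
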
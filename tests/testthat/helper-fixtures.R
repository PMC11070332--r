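# Shared fixtures. Expensive objects (the default synthetic cohort and
# the fitted pipeline) are built lazily once per test run and reused.

.cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .cache)) assign(name, builder(), envir = .cache)
  get(name, envir = .cache)
}

# a tiny deterministic feature table
tiny_table <- function(n = 4, k = 3, seed = 99) {
  set.seed(seed)
  feature_table(matrix(abs(rnorm(n * k, 1000, 100)), n, k),
                feature_mz = seq(100, by = 10, length.out = k),
                feature_rt = seq(100, by = 50, length.out = k))
}

# small cohort for cheap structural tests
small_cohort <- function() {
  cached("small_cohort", function() {
    generate_cohort(synthetic_config(scale = 0.05, n_features = 200,
                                     n_discriminant_per_group = 8,
                                     n_confounded_per_covariate = 6,
                                     seed = 421))
  })
}

# the default-condition cohort used by the heavier recovery properties
default_cohort <- function() {
  cached("default_cohort", function() generate_cohort(synthetic_config(seed = 2024)))
}

# fitted pipeline on the default cohort (train side) plus its validation
default_pipeline <- function() {
  cached("default_pipeline", function() {
    cohort <- default_cohort()
    split <- split_train_test(cohort, seed = 71)
    artifacts <- suppressWarnings(suppressMessages(
      run_training(split$train, pipeline_config(seed = 71))))
    validation <- suppressMessages(run_validation(split$test, artifacts))
    list(cohort = cohort, split = split, artifacts = artifacts,
         validation = validation)
  })
}

# centered/scaled matrix + labels of the default cohort (no screening),
# for latent-model properties
default_matrix <- function() {
  cached("default_matrix", function() {
    cohort <- default_cohort()
    norm <- pqn_normalize(cohort$features)$normalized
    list(x = log_uv_transform(norm)$matrix,
         groups = factor(cohort$metadata$group))
  })
}
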
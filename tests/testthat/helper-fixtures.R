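# Shared fixtures: everything is generated in code at test time.

# Scaled-down six-block layout used by the simulation-heavy tests
# (141 features; same block structure and ratios as the full 3449 layout).
test_sets <- function(base = 60L) reduced_feature_sets(base)

# Scaled training schedule for desk-scale experiments: the study protocol
# (lr 5e-5, patience 20) needs hundreds of epochs; tests compress the
# schedule (higher lr, per-phase epoch caps) without touching batch size,
# dropout or the architecture.
scaled_cfg <- function(seed, lr = 3e-3) {
  train_config(lr = lr, batch_size = 100L, max_epochs = 8L, patience = 3L,
               dropout = 0.5, seed = seed,
               pretrain_epochs = 8L, fusion_epochs = 6L, finetune_epochs = 3L)
}

# The recovery cohort stated by the acceptance criteria: 600 subjects,
# 3 balanced classes, 2-SD effects on 10% of features.
recovery_cohort <- function(seed, effect_size = 2, n = 200L) {
  generate_cohort(cohort_spec(
    n_per_group = c(NC = n, AD = n, FTD = n), sets = test_sets(),
    effect_size = effect_size, sparsity = 0.1, seed = seed))
}

# Tiny labeled records helper
toy_records <- function(n, diagnosis = "NC", seed = 1L, scans = 1L) {
  set.seed(seed)
  subject_records(
    subject_id = rep(sprintf("T%03d", seq_len(n)), each = scans),
    visit_id = rep(sprintf("V%02d", seq_len(scans)), times = n),
    diagnosis = rep(rep_len(diagnosis, n), each = scans),
    age = rep(runif(n, 55, 90), each = scans),
    sex = rep(sample(c("M", "F"), n, TRUE), each = scans),
    icv = rep(rnorm(n, 1.5e6, 1e5), each = scans),
    field_strength = rep(sample(c("1.5T", "3T"), n, TRUE), each = scans))
}

# Session-level cache so expensive acceptance computations are shared
# between criteria that reuse the same runs.
acceptance_cache <- local({
  env <- new.env(parent = emptyenv())
  function(key, compute) {
    if (!exists(key, envir = env)) assign(key, compute(), envir = env)
    get(key, envir = env)
  }
})
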
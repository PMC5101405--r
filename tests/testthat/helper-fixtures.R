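# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# a tiny enumerable CRBM: 4x4 input, one 3x3 filter, 2x2 hidden, one block
tiny_layer <- function(seed = 42, K = 1L, sd = 0.3) {
  set.seed(seed)
  new_crbm_layer(n_v = 4, n_w = 3, n_filters = K, pool = 2,
                 sparsity_target = 0.1, init_sd = sd)
}

# a small architecture for gradient checks and fast fine-tuning tests:
# 12 -> 10 -> 5 -> 4 -> 4, 2 then 3 maps, 6 FC units
tiny_config <- function() {
  list(input_side = 12L, channels = 1L, n_filters = c(2L, 3L),
       filter_sizes = c(3L, 2L), pools = c(2L, 1L),
       sparsity_targets = c(0.05, 0.05), fc_units = 6L, n_out = 1L,
       preset = "tiny")
}

# pretrained reduced-architecture model shared by tracker tests
test_model <- function() {
  memo("model", {
    ds <- make_class_dataset(20, 10, seed = 1)
    cdbn_pretrain(ds, cdbn_preset("reduced"), crbm_epochs = 15,
                  head_epochs = 300, seed = 3)$model
  })
}

# small tracker configuration for fast end-to-end runs
test_track_config <- function() {
  cfg <- default_config("reduced")
  cfg$n_particles <- 150L
  cfg$n_negative <- 20L
  cfg$update_epochs <- 5L
  cfg$update_every <- 2L
  cfg$init_epochs <- 40L
  cfg
}
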
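# Core CRBM operations: energy, block-softmax conditionals, sampling,
# reconstruction, and CD-1 training with the sparsity penalty.

test_that("energy matches hand values and the naive summation oracle", {
  # 2x2 visibles, all-off hidden: only the quadratic (and c) terms survive
  ly <- structure(list(W = array(0, c(1, 1, 1, 1)), b = 0, c_bias = 0,
                       n_v = 2L, n_w = 1L, n_h = 2L, channels = 1L,
                       n_filters = 1L, pool = 2L, n_p = 1L,
                       sparsity_target = 0.1), class = "crbm_layer")
  v <- matrix(1, 2, 2)
  h0 <- array(0, c(2, 2, 1))
  expect_equal(crbm_energy(v, h0, ly), 2.0)
  ly$c_bias <- 1
  expect_equal(crbm_energy(v, h0, ly), -2.0)

  # random tiny instances against the independent triple-loop oracle
  for (seed in 1:5) {
    lt <- tiny_layer(seed)
    set.seed(seed + 100)
    v <- matrix(rnorm(16), 4)
    units <- array(0, c(2, 2, 1))
    units[sample.int(4, 1)] <- sample(0:1, 1)
    expect_equal(crbm_energy(v, units, lt), naive_energy(v, units, lt),
                 tolerance = 1e-12)
  }

  # the block constraint is enforced
  lt <- tiny_layer(1)
  bad <- array(1, c(2, 2, 1))
  expect_error(crbm_energy(matrix(0, 4, 4), bad, lt), "block constraint")
})

test_that("hidden conditionals: closed forms, normalisation, shift invariance", {
  set.seed(9)
  ly <- new_crbm_layer(6, 3, 2, pool = 2, sparsity_target = 0.1)

  # W = 0, b = 0: uniform 5-way softmax
  ly0 <- ly; ly0$W[] <- 0; ly0$b[] <- 0
  v <- matrix(rnorm(36), 6)
  c0 <- crbm_hidden_conditionals(v, ly0)
  expect_equal(max(abs(c0$unit_probs - 0.2)), 0, tolerance = 1e-12)
  expect_equal(max(abs(c0$pool_off - 0.2)), 0, tolerance = 1e-12)

  # W = 0, b = 10: closed form e^10 / (1 + 4 e^10)
  ly10 <- ly0; ly10$b[] <- 10
  c10 <- crbm_hidden_conditionals(v, ly10)
  expect_equal(c10$unit_probs[1, 1, 1], exp(10) / (1 + 4 * exp(10)),
               tolerance = 1e-10)
  expect_equal(c10$pool_off[1, 1, 1], 1 / (1 + 4 * exp(10)),
               tolerance = 1e-10)

  # block normalisation for random parameters
  for (seed in 1:10) {
    set.seed(seed)
    lyr <- new_crbm_layer(6, 3, 3, pool = 2, sparsity_target = 0.1,
                          init_sd = 0.5)
    cc <- crbm_hidden_conditionals(matrix(rnorm(36, sd = 2), 6), lyr)
    for (k in 1:3) for (bi in 1:2) for (bj in 1:2) {
      blk <- cc$unit_probs[(bi - 1) * 2 + 1:2, (bj - 1) * 2 + 1:2, k]
      expect_equal(sum(blk) + cc$pool_off[bi, bj, k], 1, tolerance = 1e-12)
    }
  }

  # shift invariance: a constant added to every pre-activation of a block
  # (via b_k, which shifts all blocks of map k) leaves nothing unnormalised
  ly2 <- tiny_layer(3)
  v4 <- matrix(rnorm(16, sd = 3), 4)
  base <- crbm_hidden_conditionals(v4, ly2)
  ly2b <- ly2; ly2b$b <- ly2$b + 500   # would overflow a naive softmax
  shifted <- crbm_hidden_conditionals(v4, ly2b)
  expect_true(all(is.finite(shifted$unit_probs)))
  rel <- base$unit_probs / sum(base$unit_probs)
  rels <- shifted$unit_probs / sum(shifted$unit_probs)
  expect_equal(rel, rels, tolerance = 1e-9)
})

test_that("conditionals match exhaustive enumeration of the Boltzmann law", {
  for (seed in c(1, 2, 7)) {
    lt <- tiny_layer(seed, sd = 0.4)
    set.seed(seed + 50)
    v <- matrix(rnorm(16), 4)
    got <- crbm_hidden_conditionals(v, lt)
    want <- enumerate_conditionals(v, lt)
    expect_equal(got$unit_probs, want$unit_probs, tolerance = 1e-8)
    expect_equal(got$pool_off, want$pool_off, tolerance = 1e-8)
  }
  # two filter maps: 25 joint configurations
  lt2 <- tiny_layer(5, K = 2L, sd = 0.4)
  set.seed(55)
  v <- matrix(rnorm(16), 4)
  got <- crbm_hidden_conditionals(v, lt2)
  want <- enumerate_conditionals(v, lt2)
  expect_equal(got$unit_probs, want$unit_probs, tolerance = 1e-8)
  expect_equal(got$pool_off, want$pool_off, tolerance = 1e-8)
})

test_that("hidden sampling respects the block law and is reproducible", {
  ly <- tiny_layer(1)
  v <- matrix(rnorm(16), 4)
  cond <- crbm_hidden_conditionals(v, ly)

  # forced all-off block
  off <- list(unit_probs = array(0, c(2, 2, 1)),
              pool_off = array(1, c(1, 1, 1)))
  set.seed(1)
  hs <- crbm_sample_hidden(off, ly)
  expect_equal(sum(hs$units), 0)
  expect_equal(sum(hs$pool), 0)

  # empirical frequencies of the uniform 5-way block within 3 sigma
  unif <- list(unit_probs = array(0.2, c(2, 2, 1)),
               pool_off = array(0.2, c(1, 1, 1)))
  set.seed(2)
  n <- 20000L
  counts <- numeric(4)
  for (i in seq_len(n)) counts <- counts + crbm_sample_hidden(unif, ly)$units
  se3 <- 3 * sqrt(0.2 * 0.8 / n)
  expect_true(all(abs(counts / n - 0.2) < se3))

  # determinism and constraint under random conditionals
  set.seed(3); h1 <- crbm_sample_hidden(cond, ly)
  set.seed(3); h2 <- crbm_sample_hidden(cond, ly)
  expect_identical(h1, h2)
  expect_lte(sum(h1$units), 1)
  expect_equal(h1$pool[1, 1, 1], as.numeric(sum(h1$units) > 0))
})

test_that("visible conditional means are the full convolution plus bias", {
  ly <- tiny_layer(4)
  ly$c_bias <- 0.7
  h0 <- array(0, c(2, 2, 1))
  expect_equal(crbm_visible_conditionals(h0, ly),
               array(0.7, c(4, 4, 1)))
  # single active unit stamps the filter
  h1 <- array(0, c(2, 2, 1)); h1[1, 1, 1] <- 1
  m <- crbm_visible_conditionals(h1, ly)
  expect_equal(m[1:3, 1:3, 1], ly$W[, , 1, 1] + 0.7)
  expect_equal(m[4, 4, 1], 0.7)
  # random states against the naive full convolution
  for (seed in 1:3) {
    set.seed(seed)
    lt <- tiny_layer(seed + 20, K = 2L)
    u <- array(rbinom(8, 1, 0.3), c(2, 2, 2))
    expect_equal(crbm_visible_conditionals(u, lt),
                 naive_full_conv(u, lt) + lt$c_bias, tolerance = 1e-12)
  }
})

test_that("pooled representation is 1 - pool_off with the right geometry", {
  set.seed(11)
  ly <- new_crbm_layer(32, 5, 4, pool = 2, sparsity_target = 0.01)
  ly0 <- ly; ly0$W[] <- 0; ly0$b[] <- 0
  v <- matrix(rnorm(1024), 32)
  p <- crbm_pooled_representation(v, ly0)
  expect_equal(dim(p), c(14L, 14L, 4L))
  expect_equal(max(abs(p - 0.8)), 0, tolerance = 1e-12)
  cond <- crbm_hidden_conditionals(v, ly)
  expect_equal(crbm_pooled_representation(v, ly), 1 - cond$pool_off)
})

test_that("CD-1 gradient: sparsity sign and agreement with exact gradient", {
  ly <- tiny_layer(2)
  set.seed(5)
  batch <- lapply(1:4, function(i) matrix(rnorm(16), 4))

  # mean activation above target: sparsity pushes b down
  g0 <- crbm_cd1_gradient(batch, ly, sparsity_weight = 0)
  set.seed(99); g1 <- crbm_cd1_gradient(batch, ly, sparsity_weight = 0)
  expect_gt(mean(g0$mean_activation), ly$sparsity_target)
  gl <- crbm_cd1_gradient(batch, ly, sparsity_weight = 1000)
  expect_lt(mean(gl$db - g1$db), 0)

  expect_error(crbm_cd1_gradient(list(), ly), "empty")

  # averaged CD-1 increment points uphill of the exact likelihood
  # gradient (finite differences over the enumerated partition function)
  lt <- tiny_layer(8, sd = 0.2)
  set.seed(10)
  v <- matrix(rnorm(16), 4)
  get_par <- function(l) c(as.vector(l$W), l$b, l$c_bias)
  set_par <- function(l, th) {
    l$W <- array(th[1:9], c(3, 3, 1, 1)); l$b <- th[10]; l$c_bias <- th[11]
    l
  }
  th <- get_par(lt); hstep <- 1e-5
  exact <- vapply(seq_along(th), function(j) {
    tp <- th; tp[j] <- tp[j] + hstep
    tm <- th; tm[j] <- tm[j] - hstep
    (naive_loglik(v, set_par(lt, tp)) - naive_loglik(v, set_par(lt, tm))) /
      (2 * hstep)
  }, numeric(1))
  set.seed(123)
  acc <- numeric(length(th))
  for (rep in 1:200) {
    g <- crbm_cd1_gradient(list(v), lt, sparsity_weight = 0)
    acc <- acc + c(as.vector(g$dW), g$db, g$dc)
  }
  cosine <- sum(acc * exact) / sqrt(sum(acc^2) * sum(exact^2))
  expect_gt(cosine, 0)
})

test_that("layer training runs, is seed-stable, and 0 epochs is identity", {
  set.seed(6)
  data <- lapply(1:20, function(i) standardize_patch(matrix(runif(64), 8)))
  ly <- new_crbm_layer(8, 3, 2, pool = 2, sparsity_target = 0.05)
  same <- crbm_train_layer(data, ly, epochs = 0)
  expect_identical(same$layer, ly)
  expect_equal(nrow(same$trace), 0L)

  set.seed(7)
  f1 <- crbm_train_layer(data, ly, epochs = 3, sparsity_weight = 50)
  set.seed(7)
  f2 <- crbm_train_layer(data, ly, epochs = 3, sparsity_weight = 50)
  expect_identical(f1$layer, f2$layer)
  expect_equal(nrow(f1$trace), 3L)
  expect_true(all(is.finite(f1$trace$recon_error)))
})

test_that("trained mean activation decreases with the sparsity weight", {
  ds <- make_class_dataset(5, 10, side = 16, seed = 4)
  x <- lapply(ds$patches, standardize_patch)
  acts <- vapply(c(0, 100, 1000), function(w) {
    set.seed(21)
    ly <- new_crbm_layer(16, 5, 4, pool = 2, sparsity_target = 0.003)
    fit <- crbm_train_layer(x, ly, epochs = 10, sparsity_weight = w)
    crbm_mean_activation(x, fit$layer)
  }, numeric(1))
  expect_true(acts[1] > acts[2] && acts[2] > acts[3])
})
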
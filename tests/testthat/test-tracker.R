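# Particle filter mechanics, patch cropping, sample buffers and the
# tracking loop.

test_that("crop_patch reproduces content and matches the reference resampler", {
  set.seed(1)
  f <- matrix(runif(32 * 32), 32)
  # a box covering the whole 32x32 frame is pixel-identical (up to the
  # standardisation, undone here from the stored statistics)
  p <- crop_patch(f, c(0, 0, 32, 32))
  restored <- p[, , 1] * attr(p, "norm_sd") + attr(p, "norm_mean")
  expect_equal(restored, f, tolerance = 1e-12)

  # constant box: zero after standardisation
  g <- matrix(0.5, 100, 100)
  expect_equal(sum(abs(crop_patch(g, c(10, 10, 64, 64)))), 0)

  # checkerboard downsampled 2x against the independent bilinear oracle
  cb <- outer(1:64, 1:64, function(i, j) (i + j) %% 2)
  got <- crop_patch(cb, c(0, 0, 64, 64), standardize = FALSE)
  want <- naive_bilinear(cb, 0, 0, 64, 64, 32)
  expect_equal(got[, , 1], want, tolerance = 1e-12)

  # boxes outside the frame
  expect_error(crop_patch(f, c(100, 100, 10, 10)), "intersect")
  expect_error(crop_patch(f, c(0, 0, 0, 5)), "size")
})

test_that("propagation follows the Gaussian motion model", {
  ps <- particle_init(c(50, 40, 20, 10), 1000)
  expect_equal(sum(ps$weights), 1)

  # zero covariance: states unchanged
  p0 <- particle_propagate(ps, diag(0, 4))
  expect_equal(p0$states, ps$states)

  # sample moments of a diagonal covariance (CLT bounds)
  big <- particle_init(c(200, 200, 50, 50), 1e5)
  set.seed(2)
  pb <- particle_propagate(big, c(25, 25, 1, 1))
  d <- sweep(pb$states, 2, c(200, 200, 50, 50))
  expect_true(all(abs(colMeans(d)) < 3 * sqrt(c(25, 25, 1, 1) / 1e5)))
  expect_true(all(abs(apply(d, 2, var) / c(25, 25, 1, 1) - 1) < 0.05))

  set.seed(3); a <- particle_propagate(ps, c(4, 4, 1, 1))
  set.seed(3); b <- particle_propagate(ps, c(4, 4, 1, 1))
  expect_identical(a$states, b$states)
  expect_error(particle_propagate(ps, matrix(c(1, 2, 0, 0), 2, 2)),
               "symmetric|PSD|covariance")
})

test_that("weighting multiplies by confidence and renormalises", {
  set.seed(4)
  m <- cdbn_transfer_output(cdbn_build(cdbn_preset("reduced")), 1L)
  f <- matrix(runif(120 * 160), 120, 160)
  ps <- particle_init(c(60, 50, 24, 24), 20)
  ps$states <- ps$states + matrix(rnorm(80, sd = 5), 20)
  pw <- particle_weigh(ps, f, m)
  expect_equal(sum(pw$weights), 1, tolerance = 1e-12)
  expect_true(all(pw$confidences > 0 & pw$confidences < 1))
  # equal confidences leave normalised weights unchanged
  m0 <- m; m0$out_W[] <- 0; m0$fc_W[] <- 0
  pe <- particle_weigh(ps, f, m0)
  expect_equal(pe$weights, rep(1 / 20, 20), tolerance = 1e-12)
})

test_that("best state is the argmax with lowest-index tie-breaking", {
  ps <- particle_init(c(0, 0, 5, 5), 3)
  ps$states[2, ] <- c(9, 9, 5, 5)
  ps$weights <- c(0.1, 0.7, 0.2)
  expect_equal(unname(particle_best(ps)), c(9, 9, 5, 5))
  ps$weights <- rep(1 / 3, 3)
  expect_equal(unname(particle_best(ps)), c(0, 0, 5, 5))
  for (i in 1:10) {
    set.seed(i)
    w <- runif(3); ps$weights <- w / sum(w)
    expect_equal(unname(particle_best(ps)),
                 unname(ps$states[which.max(ps$weights), ]))
  }
})

test_that("resampling triggers on ESS and is multinomially correct", {
  ps <- particle_init(c(0, 0, 5, 5), 10)
  for (i in 1:10) ps$states[i, 1] <- i
  ps$confidences <- rep(0.5, 10)

  # uniform weights: untouched
  pu <- particle_resample(ps)
  expect_false(attr(pu, "resampled"))
  expect_equal(pu$states, ps$states)

  # degenerate weights: N copies of the surviving particle
  pd <- ps; pd$weights <- c(1, rep(0, 9))
  set.seed(5)
  pr <- particle_resample(pd)
  expect_true(attr(pr, "resampled"))
  expect_true(all(pr$states[, 1] == 1))
  expect_equal(pr$weights, rep(0.1, 10))

  # resampled index frequencies match the multinomial expectation
  pm <- ps; pm$weights <- c(0.5, 0.3, 0.1, 0.1, rep(0, 6))
  set.seed(6)
  counts <- numeric(10)
  trials <- 2000L
  for (i in seq_len(trials)) {
    r <- particle_resample(pm)
    counts <- counts + tabulate(attr(r, "indices"), 10)
  }
  n <- trials * 10
  p <- pm$weights
  for (j in 1:4)
    expect_lt(abs(counts[j] / n - p[j]), 3 * sqrt(p[j] * (1 - p[j]) / n))
  expect_equal(sum(counts[5:10]), 0)
})

test_that("positive harvesting returns the top-confidence distinct boxes", {
  set.seed(7)
  m <- cdbn_transfer_output(cdbn_build(cdbn_preset("reduced")), 1L)
  f <- matrix(runif(120 * 160), 120, 160)
  ps <- particle_init(c(60, 50, 24, 24), 40)
  ps$states <- ps$states + matrix(rnorm(160, sd = 6), 40)
  ps <- particle_weigh(ps, f, m)
  top <- harvest_positives(f, ps, m, n = 10)
  expect_length(top, 10L)
  confs <- vapply(top, `[[`, numeric(1), "confidence")
  expect_true(all(diff(confs) <= 0))
  expect_gte(min(confs), sort(ps$confidences, decreasing = TRUE)[11])

  # duplicated boxes collapse
  ps2 <- particle_init(c(60, 50, 24, 24), 40)   # all states identical
  ps2 <- particle_weigh(ps2, f, m)
  expect_length(harvest_positives(f, ps2, m, n = 10), 1L)
})

test_that("negative harvesting respects the IoU bound and the seed", {
  set.seed(8)
  m <- cdbn_transfer_output(cdbn_build(cdbn_preset("reduced")), 1L)
  f <- matrix(runif(240 * 320), 240, 320)
  best <- c(150, 110, 24, 24)
  set.seed(9)
  negs <- harvest_negatives(f, best, m, n = 100)
  expect_length(negs, 100L)
  for (s in negs) expect_lt(box_iou(s$box, best), 0.3)
  set.seed(9)
  negs2 <- harvest_negatives(f, best, m, n = 100)
  expect_identical(lapply(negs, `[[`, "box"), lapply(negs2, `[[`, "box"))
})

test_that("sample buffers implement the FIFO and immutability contracts", {
  gt <- list(list(patch = matrix(1, 2, 2), box = c(0, 0, 2, 2)))
  buf <- sample_buffers(gt, capacity = 25)
  gt_snapshot <- buf$ground_truth
  for (t in 2:40) {
    buf <- update_buffers(buf, matrix(t, 2, 2), t)
    expect_equal(length(buf$long_term), min(t - 1, 25))
  }
  frames <- vapply(buf$long_term, `[[`, integer(1), "frame")
  expect_equal(frames, 16:40)
  expect_identical(buf$ground_truth, gt_snapshot)
})

test_that("model update uses the buffers and 0 epochs is the identity", {
  set.seed(10)
  m <- cdbn_build(tiny_config(), init_sd = 0.1)   # single-unit head
  mk <- function(fg) {
    p <- matrix(rnorm(144, sd = 0.1), 12)
    if (fg) p[4:9, 4:9] <- p[4:9, 4:9] + 2
    standardize_patch(p)
  }
  buf <- sample_buffers(lapply(1:3, function(i)
    list(patch = mk(TRUE), box = c(0, 0, 12, 12))), 25)
  buf$negatives <- lapply(1:6, function(i)
    list(patch = mk(FALSE), box = c(20, 20, 12, 12)))
  expect_identical(update_model(m, buf, epochs = 0), m)
  expect_error(update_model(m, sample_buffers(buf$ground_truth, 25),
                            epochs = 1), "negatives")
  conf_before <- mean(vapply(buf$ground_truth, function(s)
    cdbn_confidence(m, s$patch), numeric(1)))
  set.seed(11)
  m2 <- update_model(m, buf, epochs = 150)
  conf_after <- mean(vapply(buf$ground_truth, function(s)
    cdbn_confidence(m2, s$patch), numeric(1)))
  expect_gte(conf_after, conf_before)
})

test_that("a static target with zero motion noise is tracked exactly", {
  sc <- sequence_scenario(width = 120, height = 100, n_frames = 6,
                          start = c(40, 40), velocity = c(0, 0),
                          noise_sd = 0, seed = 2)
  sq <- make_sequence(sc)
  m <- cdbn_transfer_output(cdbn_build(cdbn_preset("reduced")), 1L)
  cfg <- test_track_config()
  cfg$motion_sigma <- diag(0, 4)
  cfg$n_particles <- 20L
  cfg$init_epochs <- 5L
  cfg$update_epochs <- 0L
  res <- track(sq$frames, as.numeric(sq$gt[1, ]), m, config = cfg, seed = 12)
  expect_equal(nrow(res), 6L)
  expect_equal(max(center_error(res, sq$gt)), 0)
})

test_that("tracking runs are reproducible under a fixed seed", {
  sq <- make_sequence(sequence_scenario(width = 160, height = 120,
                                        n_frames = 5, start = c(50, 50),
                                        velocity = c(2, 1), seed = 3))
  m <- test_model()
  cfg <- test_track_config()
  cfg$n_particles <- 60L
  cfg$init_epochs <- 10L
  cfg$update_epochs <- 2L
  r1 <- track(sq$frames, as.numeric(sq$gt[1, ]), m, config = cfg, seed = 13)
  r2 <- track(sq$frames, as.numeric(sq$gt[1, ]), m, config = cfg, seed = 13)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})
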
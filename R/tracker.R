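# Particle-filter tracking with the CDBN appearance model and the
# three-tier positive-sample update strategy (ground-truth / long-term FIFO
# / short-term).  States are bounding boxes x_t = (x, y, w, h), 0-based
# top-left origin, continuous-valued.

#' Bilinear crop of a bounding box to a 32x32 observation patch
#'
#' Clips the box to the frame, resamples its content to the model's input
#' side with bilinear interpolation (pixel centers aligned), and
#' standardises the result to zero mean and unit variance.
#'
#' @param frame Grayscale matrix (H x W, values in any range) or
#'   H x W x C array.
#' @param state Numeric `c(x, y, w, h)` bounding box (0-based top-left).
#' @param side Output side length (default 32).
#' @param standardize Standardise after resampling (default TRUE).
#' @return `side x side x C` array (standardised patch).
#' @export
crop_patch <- function(frame, state, side = 32L, standardize = TRUE) {
  if (is.matrix(frame)) frame <- array(frame, dim = c(dim(frame), 1L))
  H <- dim(frame)[1]; W <- dim(frame)[2]; nc <- dim(frame)[3]
  x0 <- state[1]; y0 <- state[2]; w <- state[3]; h <- state[4]
  if (w <= 0 || h <= 0) stop("box has non-positive size")
  x1 <- max(x0, 0); y1 <- max(y0, 0)
  x2 <- min(x0 + w, W); y2 <- min(y0 + h, H)
  if (x2 - x1 <= 0 || y2 - y1 <= 0)
    stop("box does not intersect the frame")
  # sample positions: centers of `side` cells spanning the clipped box,
  # in 1-based continuous pixel coordinates of the frame
  xs <- x1 + (seq_len(side) - 0.5) * (x2 - x1) / side + 0.5
  ys <- y1 + (seq_len(side) - 0.5) * (y2 - y1) / side + 0.5
  xs <- pmin(pmax(xs, 1), W); ys <- pmin(pmax(ys, 1), H)
  ix <- pmin(floor(xs), W - 1L); iy <- pmin(floor(ys), H - 1L)
  fx <- xs - ix; fy <- ys - iy
  out <- array(0, dim = c(side, side, nc))
  wy0 <- (1 - fy); wy1 <- fy
  for (c in seq_len(nc)) {
    ch <- frame[, , c]
    v00 <- ch[cbind(rep(iy, side), rep(ix, each = side))]
    v10 <- ch[cbind(rep(iy + 1L, side), rep(ix, each = side))]
    v01 <- ch[cbind(rep(iy, side), rep(ix + 1L, each = side))]
    v11 <- ch[cbind(rep(iy + 1L, side), rep(ix + 1L, each = side))]
    wx0 <- rep(1 - fx, each = side); wx1 <- rep(fx, each = side)
    out[, , c] <- matrix(
      v00 * wy0 * wx0 + v10 * wy1 * wx0 + v01 * wy0 * wx1 + v11 * wy1 * wx1,
      nrow = side)
  }
  if (standardize) standardize_patch(out) else out
}

#' Initialise a particle set
#'
#' All particles start at the given state with uniform weights.
#'
#' @param state Numeric `c(x, y, w, h)`.
#' @param n Number of particles.
#' @return A `particle_set`: `states` (n x 4 matrix), `weights`
#'   (sum to one), `confidences`.
#' @export
particle_init <- function(state, n = 1000L) {
  structure(list(
    states = matrix(rep(as.numeric(state), each = n), nrow = n,
                    dimnames = list(NULL, c("x", "y", "w", "h"))),
    weights = rep(1 / n, n),
    confidences = rep(NA_real_, n)
  ), class = "particle_set")
}

#' Propagate particles through the Gaussian motion model
#'
#' Perturbs every state by a draw from `N(0, Sigma)` over (x, y, w, h);
#' weights are untouched.  Widths/heights are floored at 2 px.
#'
#' @param particles A `particle_set`.
#' @param sigma 4x4 symmetric positive-semidefinite covariance, or a
#'   length-4 vector of variances.
#' @return The propagated `particle_set`.
#' @export
particle_propagate <- function(particles, sigma) {
  n <- nrow(particles$states)
  if (is.vector(sigma) && length(sigma) == 4L) sigma <- diag(sigma, 4L)
  if (!isTRUE(all.equal(sigma, t(sigma))))
    stop("motion covariance must be symmetric")
  ev <- eigen(sigma, symmetric = TRUE)
  if (any(ev$values < -1e-8)) stop("motion covariance must be PSD")
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 4L)
  noise <- matrix(rnorm(n * 4L), ncol = 4L) %*% t(rt)
  particles$states <- particles$states + noise
  particles$states[, 3:4] <- pmax(particles$states[, 3:4], 2)
  particles$confidences <- rep(NA_real_, n)
  particles
}

#' Weigh particles by the appearance-model likelihood
#'
#' Multiplies every weight by the CDBN confidence of the particle's patch
#' (`w_t^i = w_{t-1}^i p(y_t | x_t^i)`) and renormalises.  Particles whose
#' boxes miss the frame get zero likelihood.  If all likelihoods vanish
#' numerically the weights are reset to uniform with a warning.
#'
#' @param particles A `particle_set`.
#' @param frame The current frame.
#' @param model A transferred `cdbn_model` (`n_out = 1`).
#' @return `particle_set` with updated normalised `weights` and per-particle
#'   `confidences`.
#' @export
particle_weigh <- function(particles, frame, model) {
  n <- nrow(particles$states)
  side <- model$input_side
  conf <- numeric(n)
  for (i in seq_len(n)) {
    conf[i] <- tryCatch(
      cdbn_confidence(model, crop_patch(frame, particles$states[i, ], side)),
      error = function(e) 0)
  }
  particles$confidences <- conf
  w <- particles$weights * conf
  s <- sum(w)
  if (s <= 0 || !is.finite(s)) {
    warning("all particle likelihoods are numerically zero; ",
            "resetting to uniform weights")
    particles$weights <- rep(1 / n, n)
  } else {
    particles$weights <- w / s
  }
  particles
}

#' Highest-weight particle state
#'
#' @param particles A `particle_set`.
#' @return Named numeric `c(x, y, w, h)` of the maximum-weight particle;
#'   ties go to the lowest particle index.
#' @export
particle_best <- function(particles) {
  if (nrow(particles$states) == 0L) stop("empty particle set")
  particles$states[which.max(particles$weights), ]
}

#' Effective sample size of a weight vector
#' @param weights Normalised particle weights.
#' @return `1 / sum(w^2)`, in `[1, N]`.
#' @export
effective_sample_size <- function(weights) 1 / sum(weights^2)

#' Multinomial resampling when the weights degenerate
#'
#' The spread of the normalised weights is monitored through the effective
#' sample size `N_eff = 1 / sum(w_i^2)` (a monotone transform of the weight
#' variance).  When it falls below `ess_frac * N`, N indices are drawn
#' multinomially proportional to the weights and all weights reset to 1/N.
#'
#' @param particles A `particle_set` with normalised weights.
#' @param ess_frac Resampling threshold as a fraction of N (default 0.5).
#' @return `particle_set`; attribute `resampled` (logical) and, when
#'   resampling occurred, `indices` (the drawn beta_j).
#' @export
particle_resample <- function(particles, ess_frac = 0.5) {
  n <- nrow(particles$states)
  if (effective_sample_size(particles$weights) < ess_frac * n) {
    idx <- sample.int(n, n, replace = TRUE, prob = particles$weights)
    particles$states <- particles$states[idx, , drop = FALSE]
    particles$confidences <- particles$confidences[idx]
    particles$weights <- rep(1 / n, n)
    attr(particles, "resampled") <- TRUE
    attr(particles, "indices") <- idx
  } else {
    attr(particles, "resampled") <- FALSE
  }
  particles
}

#' Short-term positives: the highest-confidence particle patches
#'
#' Returns the patches of the `n` highest-confidence particles of the
#' current frame (after removing duplicate boxes left by resampling); the
#' short-term tier of the update strategy.
#'
#' @param frame Current frame.
#' @param particles A weighed `particle_set` (confidences present).
#' @param model The appearance model (for the patch side).
#' @param n Number of samples (default 10).
#' @return List of `list(patch, box, confidence)`, confidences
#'   non-increasing.
#' @export
harvest_positives <- function(frame, particles, model, n = 10L) {
  stopifnot(!anyNA(particles$confidences))
  keep <- !duplicated(particles$states)
  states <- particles$states[keep, , drop = FALSE]
  conf <- particles$confidences[keep]
  ord <- order(conf, decreasing = TRUE)
  ord <- ord[seq_len(min(n, length(ord)))]
  lapply(ord, function(i) {
    list(patch = crop_patch(frame, states[i, ], model$input_side),
         box = states[i, ], confidence = conf[i])
  })
}

#' Negative samples from an annulus around the tracked box
#'
#' Draws boxes of the tracked size at centre distances in
#' `radii * max(w, h)` from the tracked centre, keeps those with
#' IoU < `iou_max` against it after clipping to the frame, until `n` are
#' collected (or a try budget is exhausted, with a warning).
#'
#' @param frame Current frame.
#' @param best Tracked box `c(x, y, w, h)`.
#' @param model The appearance model.
#' @param n Number of negatives (default 100).
#' @param iou_max Maximum allowed overlap with `best` (default 0.3).
#' @param radii Annulus radii as multiples of `max(w, h)` (default
#'   `c(0.5, 2)`).
#' @return List of `list(patch, box)`.
#' @export
harvest_negatives <- function(frame, best, model, n = 100L, iou_max = 0.3,
                              radii = c(0.5, 2)) {
  H <- dim(frame)[1]; W <- dim(frame)[2]
  w <- best[3]; h <- best[4]
  cx <- best[1] + w / 2; cy <- best[2] + h / 2
  out <- vector("list", n); got <- 0L; tries <- 0L
  max_tries <- 50L * n
  while (got < n && tries < max_tries) {
    tries <- tries + 1L
    r <- runif(1, radii[1], radii[2]) * max(w, h)
    th <- runif(1, 0, 2 * pi)
    bx <- cx + r * cos(th) - w / 2
    by <- cy + r * sin(th) - h / 2
    # clip to the frame
    bx <- min(max(bx, 0), W - w); by <- min(max(by, 0), H - h)
    if (W <= w || H <= h) break
    box <- c(x = bx, y = by, w = w, h = h)
    if (box_iou(box, best) >= iou_max) next
    got <- got + 1L
    out[[got]] <- list(patch = crop_patch(frame, box, model$input_side),
                       box = box)
  }
  if (got < n)
    warning("could only place ", got, " of ", n, " negative samples")
  out[seq_len(got)]
}

#' Create the sample buffers of the update strategy
#'
#' @param ground_truth List of first-frame positive samples (immutable).
#' @param capacity FIFO capacity T of the long-term buffer (default 25).
#' @return A `sample_buffers` object with tiers `ground_truth`,
#'   `long_term`, `short_term`, `negatives`.
#' @export
sample_buffers <- function(ground_truth, capacity = 25L) {
  structure(list(ground_truth = ground_truth, long_term = list(),
                 short_term = list(), negatives = list(),
                 capacity = as.integer(capacity)),
            class = "sample_buffers")
}

#' Append the tracked patch to the long-term FIFO
#'
#' Appends the current best-state patch to the long-term buffer and, if
#' its size exceeds the capacity T, keeps only the most recent T entries.
#' The ground-truth tier is never touched.
#'
#' @param buffers A `sample_buffers`.
#' @param best_patch The tracked patch of the current frame.
#' @param frame_index Its frame index (stored with the sample).
#' @return Updated `sample_buffers`.
#' @export
update_buffers <- function(buffers, best_patch, frame_index) {
  buffers$long_term <- c(buffers$long_term,
                         list(list(patch = best_patch,
                                   frame = as.integer(frame_index))))
  k <- length(buffers$long_term)
  if (k > buffers$capacity)
    buffers$long_term <- buffers$long_term[(k - buffers$capacity + 1L):k]
  buffers
}

#' Fine-tune the appearance model on the sample buffers
#'
#' Positives are the union of the configured tiers (ground-truth,
#' long-term, short-term) labelled 1; the negatives are labelled 0.
#'
#' @param model Transferred `cdbn_model`.
#' @param buffers A `sample_buffers` (with `short_term` and `negatives`
#'   filled for the current frame).
#' @param epochs Per-frame fine-tuning epochs (default 500).
#' @param learning_rate,momentum,batch_size SGD settings.
#' @param tiers Character subset of
#'   `c("ground_truth", "long_term", "short_term")` to use as positives.
#' @return The updated `cdbn_model`.
#' @export
update_model <- function(model, buffers, epochs = 500L, learning_rate = 0.1,
                         momentum = 0.5, batch_size = 64L,
                         tiers = c("ground_truth", "long_term",
                                   "short_term")) {
  if (epochs == 0L) return(model)
  pos <- list()
  for (tier in tiers) pos <- c(pos, lapply(buffers[[tier]], `[[`, "patch"))
  neg <- lapply(buffers$negatives, `[[`, "patch")
  if (length(neg) == 0L) stop("cannot update the model without negatives")
  if (length(pos) == 0L) stop("cannot update the model without positives")
  patches <- c(pos, neg)
  labels <- c(rep(1, length(pos)), rep(0, length(neg)))
  cdbn_finetune(model, patches, labels, epochs = epochs,
                learning_rate = learning_rate, momentum = momentum,
                batch_size = batch_size)$model
}

#' Track a target through an image sequence
#'
#' Runs the full tracking loop: the appearance model is fine-tuned on
#' first-frame positives (the init box plus one-pixel jitters) and annulus
#' negatives, a particle set is initialised at the init box, and every
#' subsequent frame is processed by Gaussian prediction, likelihood
#' weighting, argmax state extraction, ESS-triggered multinomial
#' resampling, sample harvesting and model update.
#'
#' @param frames List of frames (grayscale matrices or H x W x C arrays,
#'   all the same size), or a directory path readable by [read_frames()].
#' @param init_box Numeric `c(x, y, w, h)` in frame 1 (0-based).
#' @param model A pretrained `cdbn_model`; it is transferred to a
#'   single-unit head internally if needed.
#' @param config Tracker configuration, see [default_config()].
#' @param seed Optional integer seed controlling all randomness of the run.
#' @return A `track_result`: data frame with one row per frame (`frame`,
#'   `x`, `y`, `w`, `h`, `confidence`, `ess`, `resampled`), with the final
#'   buffers and diagnostics attached as attributes.
#' @export
track <- function(frames, init_box, model, config = default_config(),
                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(frames)) frames <- read_frames(frames)
  stopifnot(length(frames) >= 2L)
  cfg <- config
  f1 <- prep_frame(frames[[1L]], model)
  H <- dim(f1)[1]; W <- dim(f1)[2]
  init_box <- as.numeric(init_box)
  if (init_box[1] < 0 || init_box[2] < 0 ||
      init_box[1] + init_box[3] > W || init_box[2] + init_box[4] > H)
    stop("init box is not inside the first frame")
  if (model$n_out != 1L) model <- cdbn_transfer_output(model, 1L)

  # ground-truth positives: the init box plus 4 one-pixel jitters
  jit <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  gt <- lapply(seq_len(nrow(jit)), function(i) {
    b <- init_box + c(jit[i, ], 0, 0)
    b[1] <- min(max(b[1], 0), W - b[3]); b[2] <- min(max(b[2], 0), H - b[4])
    list(patch = crop_patch(f1, b, model$input_side), box = b)
  })
  buffers <- sample_buffers(gt, capacity = cfg$buffer_capacity)
  buffers$negatives <- harvest_negatives(f1, init_box, model,
                                         n = cfg$n_negative,
                                         iou_max = cfg$negative_iou_max)
  model <- update_model(model, buffers, epochs = cfg$init_epochs,
                        learning_rate = cfg$learning_rate,
                        momentum = cfg$momentum,
                        batch_size = cfg$batch_size,
                        tiers = "ground_truth")

  sigma <- motion_covariance(cfg, init_box)
  particles <- particle_init(init_box, n = cfg$n_particles)
  nf <- length(frames)
  res <- data.frame(frame = seq_len(nf), x = NA_real_, y = NA_real_,
                    w = NA_real_, h = NA_real_, confidence = NA_real_,
                    ess = NA_real_, resampled = FALSE)
  res[1L, 2:5] <- init_box
  res$confidence[1L] <- cdbn_confidence(model, gt[[1L]]$patch)
  res$ess[1L] <- cfg$n_particles
  low_conf_run <- 0L; lost_frames <- integer(0)
  for (t in 2:nf) {
    ft <- prep_frame(frames[[t]], model)
    particles <- particle_propagate(particles, sigma)
    particles <- particle_weigh(particles, ft, model)
    best <- particle_best(particles)
    best_conf <- particles$confidences[which.max(particles$weights)]
    res[t, 2:5] <- best
    res$confidence[t] <- best_conf
    res$ess[t] <- effective_sample_size(particles$weights)
    particles <- particle_resample(particles, cfg$resample_ess_frac)
    res$resampled[t] <- attr(particles, "resampled")
    low_conf_run <- if (max(particles$confidences) < cfg$confidence_floor)
      low_conf_run + 1L else 0L
    if (low_conf_run >= cfg$lost_after) lost_frames <- c(lost_frames, t)
    # --- update step ---
    buffers$short_term <- harvest_positives(ft, particles, model,
                                            n = cfg$n_short_term)
    buffers$negatives <- harvest_negatives(ft, best, model,
                                           n = cfg$n_negative,
                                           iou_max = cfg$negative_iou_max)
    buffers <- update_buffers(buffers,
                              crop_patch(ft, best, model$input_side), t)
    if ((t - 2L) %% cfg$update_every == 0L)
      model <- update_model(model, buffers, epochs = cfg$update_epochs,
                            learning_rate = cfg$learning_rate,
                            momentum = cfg$momentum,
                            batch_size = cfg$batch_size,
                            tiers = cfg$positive_tiers)
  }
  structure(res, class = c("track_result", "data.frame"),
            buffers = buffers, model = model,
            diagnostics = list(lost_frames = lost_frames))
}

# frame to the channel layout of the model (grayscale models get the
# luminance of RGB frames)
prep_frame <- function(frame, model) {
  if (is.matrix(frame)) frame <- array(frame, dim = c(dim(frame), 1L))
  nc <- dim(frame)[3]
  if (nc == model$channels) return(frame)
  if (model$channels == 1L && nc == 3L) {
    g <- 0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
    return(array(g, dim = c(dim(g), 1L)))
  }
  stop("frame has ", nc, " channels but the model expects ", model$channels)
}

motion_covariance <- function(cfg, init_box) {
  if (!is.null(cfg$motion_sigma)) return(cfg$motion_sigma)
  diag(c(cfg$sigma_xy^2, cfg$sigma_xy^2,
         (cfg$sigma_scale * init_box[3])^2,
         (cfg$sigma_scale * init_box[4])^2), 4L)
}
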
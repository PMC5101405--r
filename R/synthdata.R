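# Deterministic synthetic data: a 10-class labelled 32x32 patch set for
# pretraining (a stand-in for a generic natural-image patch set) and
# cell-like tracking sequences with ground truth, emulating time-lapse
# microscopy nuisances: dense clutter, low contrast, intensity drift,
# illumination variation and occlusion.

#' Labelled multi-class patch dataset
#'
#' Each class is a parametric texture family (oriented gratings at four
#' orientations, checkerboard, centred blob, ring, bright corner, cross,
#' spot lattice) with per-sample jitter of phase/frequency/position and
#' additive Gaussian noise, so classes are learnably separable from raw
#' pixels.  Fully deterministic under the seed.
#'
#' @param n_per_class Patches per class.
#' @param n_classes Number of classes, 2..10 (default 10).
#' @param side Patch side length (default 32).
#' @param noise_sd Additive pixel noise (default 0.08).
#' @param seed Integer seed (default 1).
#' @return List with `patches` (list of side x side matrices in `[0, 1]`)
#'   and `labels` (integers `1..n_classes`), class-balanced.
#' @export
make_class_dataset <- function(n_per_class, n_classes = 10L, side = 32L,
                               noise_sd = 0.08, seed = 1L) {
  if (n_classes < 2L || n_classes > 10L) stop("n_classes must be in 2..10")
  set.seed(seed)
  xg <- matrix(rep(seq_len(side), each = side), nrow = side)   # column index
  yg <- matrix(rep(seq_len(side), times = side), nrow = side)  # row index
  u <- (xg - 0.5) / side; v <- (yg - 0.5) / side
  grating <- function(theta) {
    function() {
      f <- runif(1, 3, 5); ph <- runif(1, 0, 2 * pi)
      0.5 + 0.5 * sin(2 * pi * f * (u * cos(theta) + v * sin(theta)) + ph)
    }
  }
  fams <- list(
    grating(0), grating(pi / 4), grating(pi / 2), grating(3 * pi / 4),
    checker = function() {
      f <- runif(1, 2, 3); ph <- runif(2, 0, 2 * pi)
      0.5 + 0.5 * sin(2 * pi * f * u + ph[1]) * sin(2 * pi * f * v + ph[2])
    },
    blob = function() {
      cx <- runif(1, 0.35, 0.65); cy <- runif(1, 0.35, 0.65)
      s <- runif(1, 0.12, 0.2)
      exp(-((u - cx)^2 + (v - cy)^2) / (2 * s^2))
    },
    ring = function() {
      r0 <- runif(1, 0.25, 0.35); wd <- runif(1, 0.04, 0.08)
      r <- sqrt((u - 0.5)^2 + (v - 0.5)^2)
      exp(-(r - r0)^2 / (2 * wd^2))
    },
    corner = function() {
      cx <- runif(1, 0.4, 0.6); cy <- runif(1, 0.4, 0.6)
      k <- runif(1, 15, 25)
      1 / (1 + exp(-k * (u - cx))) * 1 / (1 + exp(-k * (v - cy)))
    },
    cross = function() {
      cx <- runif(1, 0.4, 0.6); cy <- runif(1, 0.4, 0.6)
      wd <- runif(1, 0.05, 0.09)
      pmin(1, exp(-(u - cx)^2 / (2 * wd^2)) + exp(-(v - cy)^2 / (2 * wd^2)))
    },
    spots = function() {
      f <- runif(1, 3.5, 4.5); ph <- runif(2, 0, 2 * pi)
      (0.5 + 0.5 * sin(2 * pi * f * u + ph[1]))^3 *
        (0.5 + 0.5 * sin(2 * pi * f * v + ph[2]))^3
    }
  )
  patches <- vector("list", n_per_class * n_classes)
  labels <- integer(length(patches))
  k <- 0L
  for (cls in seq_len(n_classes)) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      p <- fams[[cls]]() + rnorm(side * side, sd = noise_sd)
      patches[[k]] <- matrix(pmin(pmax(p, 0), 1), nrow = side)
      labels[k] <- cls
    }
  }
  list(patches = patches, labels = labels)
}

#' Define a tracking-sequence scenario
#'
#' Validates that the target's box stays at least one pixel inside the
#' frame for the whole motion.
#'
#' @param width,height Frame size in pixels (default 320 x 240).
#' @param n_frames Number of frames.
#' @param start Target centre `c(x, y)` in frame 1 (0-based pixels).
#' @param velocity Per-frame centre displacement `c(vx, vy)`.
#' @param sinusoidal Optional list `list(amplitude, period)` adding a
#'   vertical sinusoid to the linear path.
#' @param radius Target blob radius (Gaussian sigma is `radius / 2`); the
#'   ground-truth box side is `2 * radius`.
#' @param intensity Target peak intensity above background.
#' @param drift Per-frame linear fade of the target intensity (appearance
#'   drift rate; 0 = constant appearance).
#' @param background Background level in `[0, 1]`.
#' @param illumination Optional `list(amplitude, period)`: a spatial
#'   illumination plane whose orientation rotates over frames.
#' @param noise_sd Additive Gaussian pixel noise.
#' @param n_clutter Number of clutter blobs performing random walks.
#' @param clutter_contrast Clutter intensity relative to the target's.
#' @param occluder Optional `list(start, duration, intensity, scale)`: an
#'   opaque rectangle `scale` times the target box, centred on the target,
#'   during frames `start .. start + duration - 1`.
#' @param seed Integer seed.
#' @return A validated `sequence_scenario` list.
#' @export
sequence_scenario <- function(width = 320L, height = 240L, n_frames = 60L,
                              start = c(60, 60), velocity = c(2, 1),
                              sinusoidal = NULL, radius = 12,
                              intensity = 0.55, drift = 0,
                              background = 0.25, illumination = NULL,
                              noise_sd = 0.01, n_clutter = 0L,
                              clutter_contrast = 0.8, occluder = NULL,
                              seed = 1L) {
  sc <- list(width = as.integer(width), height = as.integer(height),
             n_frames = as.integer(n_frames), start = start,
             velocity = velocity, sinusoidal = sinusoidal, radius = radius,
             intensity = intensity, drift = drift, background = background,
             illumination = illumination, noise_sd = noise_sd,
             n_clutter = as.integer(n_clutter),
             clutter_contrast = clutter_contrast, occluder = occluder,
             seed = as.integer(seed))
  ctr <- scenario_centers(sc)
  half <- radius
  if (any(ctr[, 1] - half < 1) || any(ctr[, 1] + half > width - 1) ||
      any(ctr[, 2] - half < 1) || any(ctr[, 2] + half > height - 1))
    stop("motion spec pushes the target box out of the frame")
  structure(sc, class = "sequence_scenario")
}

scenario_centers <- function(sc) {
  t <- seq_len(sc$n_frames) - 1
  cx <- sc$start[1] + sc$velocity[1] * t
  cy <- sc$start[2] + sc$velocity[2] * t
  if (!is.null(sc$sinusoidal))
    cy <- cy + sc$sinusoidal$amplitude *
      sin(2 * pi * t / sc$sinusoidal$period)
  cbind(cx, cy)
}

#' Render a synthetic tracking sequence
#'
#' Renders the moving Gaussian-blob target with the scenario's nuisances
#' (clutter random walks, rotating illumination plane, intensity drift,
#' occluder), adds noise, and quantises each frame to 8 bits.
#'
#' @param scenario A [sequence_scenario()].
#' @return List with `frames` (list of H x W matrices in `[0, 1]`), `gt`
#'   (ground-truth trajectory data frame `x, y, w, h`, 0-based), and
#'   `occluded` (logical per-frame flag).
#' @export
make_sequence <- function(scenario) {
  sc <- scenario
  set.seed(sc$seed)
  W <- sc$width; H <- sc$height
  xg <- matrix(rep(seq_len(W) - 1, each = H), nrow = H)
  yg <- matrix(rep(seq_len(H) - 1, times = W), nrow = H)
  ctr <- scenario_centers(sc)
  sig <- sc$radius / 2
  # clutter initial positions and random-walk steps, drawn up front
  if (sc$n_clutter > 0L) {
    cl_pos <- cbind(runif(sc$n_clutter, 10, W - 10),
                    runif(sc$n_clutter, 10, H - 10))
    cl_r <- sc$radius * runif(sc$n_clutter, 0.6, 1.3)
    cl_int <- sc$intensity * sc$clutter_contrast *
      runif(sc$n_clutter, 0.6, 1)
    cl_steps <- array(rnorm(sc$n_clutter * 2 * sc$n_frames, sd = 1.5),
                      dim = c(sc$n_clutter, 2, sc$n_frames))
  }
  frames <- vector("list", sc$n_frames)
  occluded <- logical(sc$n_frames)
  for (t in seq_len(sc$n_frames)) {
    f <- matrix(sc$background, nrow = H, ncol = W)
    if (!is.null(sc$illumination)) {
      phi <- 2 * pi * (t - 1) / sc$illumination$period
      f <- f + sc$illumination$amplitude *
        ((xg / W) * cos(phi) + (yg / H) * sin(phi))
    }
    if (sc$n_clutter > 0L) {
      cl_pos <- cl_pos + cl_steps[, , t, drop = FALSE][, , 1]
      cl_pos[, 1] <- pmin(pmax(cl_pos[, 1], 5), W - 5)
      cl_pos[, 2] <- pmin(pmax(cl_pos[, 2], 5), H - 5)
      for (i in seq_len(sc$n_clutter)) {
        s <- cl_r[i] / 2
        f <- f + cl_int[i] *
          exp(-((xg - cl_pos[i, 1])^2 + (yg - cl_pos[i, 2])^2) / (2 * s^2))
      }
    }
    amp <- sc$intensity * max(1 - sc$drift * (t - 1), 0.3)
    f <- f + amp * exp(-((xg - ctr[t, 1])^2 + (yg - ctr[t, 2])^2) /
                         (2 * sig^2))
    if (!is.null(sc$occluder) &&
        t >= sc$occluder$start &&
        t < sc$occluder$start + sc$occluder$duration) {
      occluded[t] <- TRUE
      half <- sc$radius * (sc$occluder$scale %||% 1.5)
      ox <- xg >= ctr[t, 1] - half & xg <= ctr[t, 1] + half &
            yg >= ctr[t, 2] - half & yg <= ctr[t, 2] + half
      f[ox] <- sc$occluder$intensity %||% 0.55
    }
    f <- f + rnorm(H * W, sd = sc$noise_sd)
    frames[[t]] <- round(pmin(pmax(f, 0), 1) * 255) / 255
  }
  gt <- data.frame(x = ctr[, 1] - sc$radius, y = ctr[, 2] - sc$radius,
                   w = 2 * sc$radius, h = 2 * sc$radius)
  list(frames = frames, gt = gt, occluded = occluded, scenario = sc)
}

#' Named scenario presets
#'
#' Ships the standard test-bed scenarios, all 60 frames at 320 x 240:
#' `"linear-clean"` (constant-appearance target, no nuisances),
#' `"illumination-ramp"` (rotating illumination plane), `"occlusion-10"`
#' (a full 10-frame occlusion mid-sequence), and `"cell-dense"` (many
#' low-contrast clutter blobs, low-contrast target, mild illumination
#' variation — the microscopy-like regime).
#'
#' @param seed Base seed applied to every preset (default 101).
#' @return Named list of `sequence_scenario` objects.
#' @export
sequence_presets <- function(seed = 101L) {
  list(
    "linear-clean" = sequence_scenario(seed = seed),
    "illumination-ramp" = sequence_scenario(
      illumination = list(amplitude = 0.2, period = 40),
      noise_sd = 0.02, seed = seed + 1L),
    "occlusion-10" = sequence_scenario(
      occluder = list(start = 25L, duration = 10L, intensity = 0.55,
                      scale = 1.5),
      seed = seed + 2L),
    "cell-dense" = sequence_scenario(
      background = 0.35, intensity = 0.18, radius = 10,
      n_clutter = 40L, clutter_contrast = 0.8,
      illumination = list(amplitude = 0.05, period = 40),
      noise_sd = 0.02, start = c(70, 70), velocity = c(1.5, 1),
      seed = seed + 3L)
  )
}
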
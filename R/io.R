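# Readers/writers, configuration and reproducibility plumbing: YAML run
# configuration with the published defaults baked in, OTB-format box
# files, CSV results, frame directories, and a text model container.

#' Default run configuration
#'
#' The `"full"` preset carries the published operating point: 1,000
#' particles, long-term buffer capacity T = 25, 10 short-term positives
#' per frame, 500 fine-tuning epochs per frame, learning rate 0.1 and
#' momentum 0.5.  The `"reduced"` preset keeps the same structure at test
#' scale (300 particles, 30 negatives, short per-frame updates) and pairs
#' with the reduced architecture of [cdbn_preset()].
#'
#' @param preset `"full"` or `"reduced"`.
#' @return Named list of tracker and training settings.
#' @export
default_config <- function(preset = c("full", "reduced")) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    n_particles = 1000L,
    buffer_capacity = 25L,
    n_short_term = 10L,
    n_negative = 100L,
    negative_iou_max = 0.3,
    sigma_xy = 6,
    sigma_scale = 0.02,
    motion_sigma = NULL,
    resample_ess_frac = 0.5,
    init_epochs = 500L,
    update_epochs = 500L,
    update_every = 1L,
    learning_rate = 0.1,
    momentum = 0.5,
    batch_size = 64L,
    confidence_floor = 0.05,
    lost_after = 5L,
    positive_tiers = c("ground_truth", "long_term", "short_term"),
    seed = NULL
  )
  if (preset == "reduced") {
    cfg$n_particles <- 300L
    cfg$n_negative <- 30L
    cfg$init_epochs <- 40L
    cfg$update_epochs <- 8L
  }
  cfg
}

#' Load a run configuration from YAML
#'
#' Unspecified fields take the defaults of the chosen preset (the `preset`
#' key in the file, else `"full"`); unknown keys and invalid values are
#' rejected with the offending field named.
#'
#' @param path Path to a YAML file (an empty file yields pure defaults).
#' @return A validated configuration list.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  preset <- raw$preset %||% "full"
  cfg <- default_config(preset)
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, raw, keep.null = TRUE)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  pos_int <- c("n_particles", "buffer_capacity", "n_short_term",
               "n_negative", "init_epochs", "update_epochs", "update_every",
               "batch_size", "lost_after")
  for (f in pos_int) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] < 0 ||
        (f %in% c("n_particles", "buffer_capacity", "update_every",
                  "batch_size") && cfg[[f]] < 1))
      stop("configuration field '", f, "' must be a positive number")
    cfg[[f]] <- as.integer(cfg[[f]])
  }
  pos_real <- c("negative_iou_max", "sigma_xy", "sigma_scale",
                "resample_ess_frac", "learning_rate", "momentum",
                "confidence_floor")
  for (f in pos_real) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] < 0)
      stop("configuration field '", f, "' must be a nonnegative number")
  }
  bad <- setdiff(cfg$positive_tiers,
                 c("ground_truth", "long_term", "short_term"))
  if (length(bad))
    stop("configuration field 'positive_tiers' has unknown tier(s): ",
         paste(bad, collapse = ", "))
  cfg
}

#' Read an OTB-format ground-truth / init-box file
#'
#' One `x,y,w,h` box per line, comma-, tab- or space-separated, 1-based
#' coordinates as used by the OTB sequences; converted to the package's
#' 0-based convention.
#'
#' @param path File path.
#' @return Data frame with columns `x, y, w, h` (0-based), one row per
#'   frame.
#' @export
read_groundtruth <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  rows <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], "[,\t ]+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 4L || anyNA(vals))
      stop("malformed box on line ", i, ": '", lines[i], "'")
    vals
  })
  m <- do.call(rbind, rows)
  data.frame(x = m[, 1] - 1, y = m[, 2] - 1, w = m[, 3], h = m[, 4])
}

#' Write boxes in OTB format (1-based)
#'
#' @param traj Trajectory data frame (`x, y, w, h`, 0-based).
#' @param path Output file path.
#' @export
write_groundtruth <- function(traj, path) {
  writeLines(sprintf("%g,%g,%g,%g",
                     traj$x + 1, traj$y + 1, traj$w, traj$h), path)
}

#' Write per-frame tracking results as CSV
#'
#' Columns: frame index, box (`x, y, w, h`) and confidence.
#'
#' @param result A `track_result` (or compatible data frame).
#' @param path Output file path.
#' @export
write_results <- function(result, path) {
  df <- as.data.frame(result)[, c("frame", "x", "y", "w", "h", "confidence")]
  write.csv(df, path, row.names = FALSE)
}

#' Read back a results CSV
#' @param path File path.
#' @return Data frame with the written columns.
#' @export
read_results <- function(path) read.csv(path)

#' Write per-frame diagnostics as JSON lines
#'
#' One JSON object per frame with the effective sample size and the
#' resampling flag, plus a final object with the lost-target frames.
#'
#' @param result A `track_result`.
#' @param path Output file path.
#' @export
write_diagnostics <- function(result, path) {
  df <- as.data.frame(result)
  lines <- vapply(seq_len(nrow(df)), function(i) {
    jsonlite::toJSON(list(frame = df$frame[i], ess = df$ess[i],
                          resampled = df$resampled[i]),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  diag <- attr(result, "diagnostics")
  if (!is.null(diag))
    lines <- c(lines, jsonlite::toJSON(diag, auto_unbox = FALSE,
                                       digits = NA))
  writeLines(lines, path)
}

#' Read a directory of image frames
#'
#' Reads PNG and TIFF frames in lexicographic filename order (JPEG is
#' supported when the EBImage package is installed).  RGB images are kept
#' as H x W x 3 arrays, grayscale as matrices, values in `[0, 1]`.
#'
#' @param dir Directory of frame files.
#' @return List of frames.
#' @export
read_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) stop("no frame files found in ", dir)
  lapply(files, read_frame)
}

read_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop("JPEG frames require the EBImage package")
      a <- EBImage::imageData(EBImage::readImage(path))
      if (length(dim(a)) == 3L) aperm(a, c(2L, 1L, 3L)) else t(a)
    },
    stop("unsupported frame format: ", ext))
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) img <- img[, , 1L]
  img
}

#' Write frames as numbered PNG files
#'
#' @param frames List of frames (matrices or H x W x 3 arrays in `[0,1]`).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_frames <- function(frames, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("frame_%04d.png", seq_along(frames)))
  for (i in seq_along(frames)) png::writePNG(frames[[i]], paths[i])
  invisible(paths)
}

# ---- model container --------------------------------------------------
# A single JSON file: a header recording the architecture, normalisation
# convention and provenance, and each parameter array as {dim, data} with
# doubles printed as %.17g so the round-trip is bit-exact.

enc_array <- function(a) list(dim = dim(a) %||% length(a),
                              data = sprintf("%.17g", as.vector(a)))

dec_array <- function(e) {
  v <- as.numeric(unlist(e$data))
  d <- as.integer(unlist(e$dim))
  if (length(d) > 1L) array(v, dim = d) else v
}

#' Save a CDBN model to a text container
#'
#' Writes a single JSON file with a header (architecture, per-patch
#' standardisation convention, provenance) and every parameter array
#' encoded at full precision, so that [load_cdbn()] restores the model
#' bit-exactly.
#'
#' @param model A `cdbn_model`.
#' @param path Output file path.
#' @export
save_cdbn <- function(model, path) {
  obj <- list(
    format = "cdbntrack-model",
    format_version = 1L,
    header = list(
      preset = model$preset,
      input_side = model$input_side,
      channels = model$channels,
      n_out = model$n_out,
      fc_units = model$fc_units,
      normalization = "per-patch zero mean, unit variance",
      provenance = model$provenance
    ),
    layers = lapply(model$layers, function(ly) list(
      n_v = ly$n_v, n_w = ly$n_w, n_h = ly$n_h, channels = ly$channels,
      n_filters = ly$n_filters, pool = ly$pool, n_p = ly$n_p,
      sparsity_target = ly$sparsity_target,
      W = enc_array(ly$W), b = enc_array(ly$b),
      c_bias = sprintf("%.17g", ly$c_bias)
    )),
    fc_W = enc_array(model$fc_W), fc_b = enc_array(model$fc_b),
    out_W = enc_array(model$out_W), out_b = enc_array(model$out_b),
    feat_mean = enc_array(model$feat_mean),
    feat_sd = enc_array(model$feat_sd)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a CDBN model from its text container
#'
#' @param path File written by [save_cdbn()].
#' @return The restored `cdbn_model`.
#' @export
load_cdbn <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$format, "cdbntrack-model"))
    stop("not a cdbntrack model file: ", path)
  hd <- obj$header
  layers <- lapply(obj$layers, function(e) {
    structure(list(
      W = dec_array(e$W), b = dec_array(e$b),
      c_bias = as.numeric(e$c_bias),
      n_v = as.integer(e$n_v), n_w = as.integer(e$n_w),
      n_h = as.integer(e$n_h), channels = as.integer(e$channels),
      n_filters = as.integer(e$n_filters), pool = as.integer(e$pool),
      n_p = as.integer(e$n_p),
      sparsity_target = as.numeric(e$sparsity_target)
    ), class = "crbm_layer")
  })
  fc_W <- dec_array(obj$fc_W)
  out_W <- dec_array(obj$out_W)
  structure(list(
    layers = layers,
    fc_W = matrix(fc_W, nrow = as.integer(hd$fc_units)),
    fc_b = dec_array(obj$fc_b),
    out_W = matrix(out_W, nrow = as.integer(hd$n_out)),
    out_b = dec_array(obj$out_b),
    feat_mean = dec_array(obj$feat_mean),
    feat_sd = dec_array(obj$feat_sd),
    input_side = as.integer(hd$input_side),
    channels = as.integer(hd$channels),
    n_out = as.integer(hd$n_out),
    fc_units = as.integer(hd$fc_units),
    preset = hd$preset,
    provenance = hd$provenance %||% list()
  ), class = "cdbn_model")
}

#' Read CIFAR-10 binary batch files
#'
#' Optional reader for the standard binary batch format (a label byte
#' followed by 3072 bytes of RGB pixel data per record), for users who
#' want to pretrain on the real dataset instead of [make_class_dataset()].
#'
#' @param path Path to a binary batch file.
#' @param n_max Maximum number of records to read (default all).
#' @return List with `patches` (32 x 32 x 3 arrays in `[0, 1]`) and
#'   `labels` (integers `1..10`).
#' @export
read_cifar10_batch <- function(path, n_max = Inf) {
  rec <- 3073L
  raw <- readBin(path, "raw", n = file.info(path)$size)
  n <- min(length(raw) %/% rec, n_max)
  if (n < 1L) stop("no complete records in ", path)
  patches <- vector("list", n); labels <- integer(n)
  for (i in seq_len(n)) {
    off <- (i - 1L) * rec
    labels[i] <- as.integer(raw[off + 1L]) + 1L
    px <- as.integer(raw[(off + 2L):(off + rec)]) / 255
    # stored row-major per channel: R, G, B planes of 32x32
    a <- array(0, dim = c(32L, 32L, 3L))
    for (ch in 1:3)
      a[, , ch] <- matrix(px[((ch - 1L) * 1024L + 1L):(ch * 1024L)],
                          nrow = 32L, byrow = TRUE)
    patches[[i]] <- a
  }
  list(patches = patches, labels = labels)
}
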
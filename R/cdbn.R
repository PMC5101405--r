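# CDBN: stacked CRBMs + fully connected head.
#
# The discriminative pass treats the block-softmax pooling probabilities as
# deterministic differentiable activations (no sampling), so the whole
# network is an ordinary feed-forward function for fine-tuning and
# confidence scoring.  All head units are logistic; training losses are
# (possibly class-weighted) cross-entropies on the logistic outputs.

#' Architecture presets
#'
#' `"full"` is the default architecture: layer 1 with 12 filters of 5x5,
#' layer 2 with 288 filters of 7x7, pooling ratio 2 at both layers,
#' sparsity targets 0.003 and 0.005, a 192-unit fully connected layer and a
#' 10-unit output.  `"reduced"` (8/32 filters, 64 FC units) keeps the same
#' geometry at a fraction of the cost and is meant for tests and quick
#' experiments.
#'
#' @param preset `"full"` or `"reduced"`.
#' @return A config list accepted by [cdbn_build()].
#' @export
cdbn_preset <- function(preset = c("full", "reduced")) {
  preset <- match.arg(preset)
  base <- list(
    input_side = 32L, channels = 1L,
    filter_sizes = c(5L, 7L), pools = c(2L, 2L),
    sparsity_targets = c(0.003, 0.005),
    n_out = 10L, preset = preset
  )
  if (preset == "full") {
    base$n_filters <- c(12L, 288L); base$fc_units <- 192L
  } else {
    base$n_filters <- c(8L, 32L); base$fc_units <- 64L
  }
  base
}

#' Build an untrained CDBN
#'
#' Stacks the configured CRBM layers (each a filter bank followed by
#' probabilistic max-pooling) and a fully connected logistic layer feeding
#' `n_out` logistic output units.  Under the full preset the spatial chain
#' is 32 -> 28 -> 14 (pool) -> 8 -> 4 (pool) with 12 then 288 maps.
#'
#' @param config A list as returned by [cdbn_preset()]; individual fields
#'   may be overridden.  `n_layers` may be set to use fewer CRBM layers
#'   than configured.
#' @param init_sd Gaussian initialisation standard deviation for all
#'   weights.
#' @return An object of class `cdbn_model`.
#' @export
cdbn_build <- function(config = cdbn_preset("full"), init_sd = 0.01) {
  cfg <- config
  n_layers <- cfg$n_layers %||% length(cfg$n_filters)
  side <- cfg$input_side
  chan <- cfg$channels
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    n_h <- side - cfg$filter_sizes[l] + 1L
    if (n_h < 1L)
      stop("layer ", l, ": filter side ", cfg$filter_sizes[l],
           " exceeds input side ", side)
    if (n_h %% cfg$pools[l] != 0L)
      stop("layer ", l, ": hidden side ", n_h,
           " is not divisible by pooling block size ", cfg$pools[l])
    layers[[l]] <- new_crbm_layer(
      n_v = side, n_w = cfg$filter_sizes[l], n_filters = cfg$n_filters[l],
      channels = chan, pool = cfg$pools[l],
      sparsity_target = cfg$sparsity_targets[l], init_sd = init_sd)
    side <- layers[[l]]$n_p
    chan <- cfg$n_filters[l]
  }
  flat <- side * side * chan
  model <- structure(list(
    layers = layers,
    fc_W = matrix(rnorm(cfg$fc_units * flat, sd = init_sd),
                  nrow = cfg$fc_units),
    fc_b = numeric(cfg$fc_units),
    out_W = matrix(rnorm(cfg$n_out * cfg$fc_units, sd = init_sd),
                   nrow = cfg$n_out),
    out_b = numeric(cfg$n_out),
    feat_mean = numeric(flat), feat_sd = rep(1, flat),
    input_side = cfg$input_side, channels = cfg$channels,
    n_out = cfg$n_out, fc_units = cfg$fc_units,
    preset = cfg$preset %||% "custom",
    provenance = list()
  ), class = "cdbn_model")
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cdbn_model <- function(x, ...) {
  cat(sprintf("CDBN appearance model (%s preset)\n", x$preset))
  side <- x$input_side
  cat(sprintf("  input %dx%dx%d\n", side, side, x$channels))
  for (l in seq_along(x$layers)) {
    ly <- x$layers[[l]]
    cat(sprintf("  CRBM %d: %d filters %dx%d, hidden %d -> pooled %d\n",
                l, ly$n_filters, ly$n_w, ly$n_w, ly$n_h, ly$n_p))
  }
  cat(sprintf("  FC: %d units; output: %d logistic unit(s)\n",
              x$fc_units, x$n_out))
  cat(sprintf("  %d trainable parameters\n", cdbn_n_parameters(x)))
  invisible(x)
}

#' Number of trainable parameters of a CDBN
#' @param model A `cdbn_model`.
#' @return Integer count over filters, biases, FC and output layers.
#' @export
cdbn_n_parameters <- function(model) {
  n <- sum(vapply(model$layers,
                  function(l) length(l$W) + length(l$b) + 1L, numeric(1)))
  as.integer(n + length(model$fc_W) + length(model$fc_b) +
               length(model$out_W) + length(model$out_b))
}

logistic <- function(z) 1 / (1 + exp(-z))

# Forward pass with cached intermediates for backprop.
cdbn_forward_cache <- function(model, v) {
  x <- v
  caches <- vector("list", length(model$layers))
  pooled <- vector("list", length(model$layers))
  for (l in seq_along(model$layers)) {
    ly <- model$layers[[l]]
    I <- cpp_corr_valid(x, ly$W)
    sm <- cpp_block_softmax(I, ly$b, ly$pool)
    p <- 1 - sm$pool_off
    caches[[l]] <- list(input = x, probs = sm$unit_probs,
                        pool_off = sm$pool_off)
    pooled[[l]] <- p
    x <- p
  }
  # standardised pooled features, winsorised so out-of-domain patches
  # cannot saturate the head
  flat_raw <- (as.vector(x) - model$feat_mean) / model$feat_sd
  flat <- pmin(pmax(flat_raw, -4), 4)
  z3 <- drop(model$fc_W %*% flat) + model$fc_b
  a3 <- logistic(z3)
  z4 <- drop(model$out_W %*% a3) + model$out_b
  a4 <- logistic(z4)
  list(layers = caches, pooled = pooled, flat = flat,
       flat_mask = (flat_raw > -4 & flat_raw < 4), a3 = a3, a4 = a4)
}

#' Deterministic forward pass
#'
#' Propagates a patch through the CRBM stack (pooling probabilities as
#' activations), the fully connected layer and the logistic output units.
#'
#' @param model A `cdbn_model`.
#' @param v Visible patch matching the model's input spec (standardised;
#'   see [standardize_patch()]).
#' @return List with `pooled` (per-layer pooled activation arrays), `fc`
#'   (FC-layer activations) and `output` (logistic outputs in (0,1)).
#' @export
cdbn_forward <- function(model, v) {
  v <- as_visible(v, model$layers[[1L]])
  fw <- cdbn_forward_cache(model, v)
  list(pooled = fw$pooled, fc = fw$a3, output = fw$a4)
}

# Backward pass; returns gradients of the summed weighted cross-entropy
# over one sample.  target: vector length n_out in {0,1}; weight: scalar.
cdbn_backward <- function(model, fw, target, weight = 1) {
  dz4 <- (fw$a4 - target) * weight
  g <- list(out_W = dz4 %o% fw$a3, out_b = dz4)
  da3 <- drop(crossprod(model$out_W, dz4))
  dz3 <- da3 * fw$a3 * (1 - fw$a3)
  g$fc_W <- dz3 %o% fw$flat
  g$fc_b <- dz3
  dflat <- drop(crossprod(model$fc_W, dz3)) * fw$flat_mask / model$feat_sd
  L <- length(model$layers)
  dW <- vector("list", L); db <- vector("list", L)
  top <- model$layers[[L]]
  dp <- array(dflat, dim = c(top$n_p, top$n_p, top$n_filters))
  for (l in rev(seq_len(L))) {
    ly <- model$layers[[l]]
    ca <- fw$layers[[l]]
    # d pool_on / dI_u = prob_u * pool_off(block)
    dI <- cpp_block_expand_mult(ca$probs, dp * ca$pool_off, ly$pool)
    dW[[l]] <- cpp_grad_filters(ca$input, dI)
    db[[l]] <- map_sums(dI)
    if (l > 1L) dp <- cpp_conv_full(dI, ly$W)
  }
  g$layer_W <- dW; g$layer_b <- db
  g
}

# cross-entropy of logistic outputs vs one-hot / binary targets
xent <- function(a, y, w = 1) {
  eps <- 1e-12
  -sum(w * (y * log(pmax(a, eps)) + (1 - y) * log(pmax(1 - a, eps))))
}

zero_grads <- function(model) {
  list(out_W = model$out_W * 0, out_b = model$out_b * 0,
       fc_W = model$fc_W * 0, fc_b = model$fc_b * 0,
       layer_W = lapply(model$layers, function(l) l$W * 0),
       layer_b = lapply(model$layers, function(l) l$b * 0))
}

add_grads <- function(a, b) {
  a$out_W <- a$out_W + b$out_W; a$out_b <- a$out_b + b$out_b
  a$fc_W <- a$fc_W + b$fc_W; a$fc_b <- a$fc_b + b$fc_b
  for (l in seq_along(a$layer_W)) {
    a$layer_W[[l]] <- a$layer_W[[l]] + b$layer_W[[l]]
    a$layer_b[[l]] <- a$layer_b[[l]] + b$layer_b[[l]]
  }
  a
}

#' Supervised fine-tuning of a CDBN
#'
#' End-to-end gradient descent with momentum on the cross-entropy of the
#' logistic outputs, backpropagated through the fully connected head and
#' (unless frozen) both CRBM stages using the deterministic forward
#' activations.  Classes are weighted inversely to their frequency so that
#' skewed online sample buffers do not collapse the model onto the
#' majority class.
#'
#' @param model A `cdbn_model`.
#' @param patches List of standardised visible patches.
#' @param labels Integer class labels `1..n_out` (multi-class) or 0/1
#'   (binary, `n_out = 1`).
#' @param epochs,learning_rate,momentum,batch_size SGD settings (defaults:
#'   500 epochs, rate 0.1, momentum 0.5, batches of 64).
#' @param freeze_crbm If `TRUE`, only the FC and output layers are updated.
#' @param clip_norm Global gradient-norm clip per minibatch (the feature
#'   standardisation can otherwise amplify gradients into the CRBM stages
#'   by orders of magnitude); `Inf` disables clipping.
#' @param class_weights Use inverse-frequency sample weights.
#' @param seed Optional integer seed for the minibatch shuffling.
#' @return List with the fine-tuned `model` and `loss` (per-epoch mean
#'   weighted cross-entropy).
#' @export
cdbn_finetune <- function(model, patches, labels, epochs = 500L,
                          learning_rate = 0.1, momentum = 0.5,
                          batch_size = 64L, freeze_crbm = FALSE,
                          clip_norm = 0.1, class_weights = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(patches)
  stopifnot(n == length(labels))
  targets <- label_targets(labels, model$n_out)
  if (length(unique(labels)) < 2L)
    stop("fine-tuning needs samples from at least two classes")
  w <- if (class_weights) {
    tab <- table(labels)
    unname(n / (length(tab) * as.numeric(tab[as.character(labels)])))
  } else rep(1, n)
  vel <- zero_grads(model)
  loss <- numeric(epochs)
  if (epochs == 0L) return(list(model = model, loss = numeric(0)))
  patches <- lapply(patches, as_visible, layer = model$layers[[1L]])
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      g <- zero_grads(model)
      for (i in idx) {
        fw <- cdbn_forward_cache(model, patches[[i]])
        tot <- tot + xent(fw$a4, targets[[i]], w[i])
        g <- add_grads(g, cdbn_backward(model, fw, targets[[i]], w[i]))
      }
      m <- length(idx)
      # per-group norm clip: the feature standardisation can blow up the
      # gradients entering the CRBM stages without affecting the head
      csc <- function(gr) {
        s <- learning_rate / m
        if (!is.finite(clip_norm)) return(s)
        gn <- sqrt(sum(gr^2)) / m
        if (gn > clip_norm) s * clip_norm / gn else s
      }
      vel$out_W <- momentum * vel$out_W - csc(g$out_W) * g$out_W
      vel$out_b <- momentum * vel$out_b - csc(g$out_b) * g$out_b
      vel$fc_W <- momentum * vel$fc_W - csc(g$fc_W) * g$fc_W
      vel$fc_b <- momentum * vel$fc_b - csc(g$fc_b) * g$fc_b
      model$out_W <- model$out_W + vel$out_W
      model$out_b <- model$out_b + vel$out_b
      model$fc_W <- model$fc_W + vel$fc_W
      model$fc_b <- model$fc_b + vel$fc_b
      if (!freeze_crbm) {
        for (l in seq_along(model$layers)) {
          vel$layer_W[[l]] <- momentum * vel$layer_W[[l]] -
            csc(g$layer_W[[l]]) * g$layer_W[[l]]
          vel$layer_b[[l]] <- momentum * vel$layer_b[[l]] -
            csc(g$layer_b[[l]]) * g$layer_b[[l]]
          model$layers[[l]]$W <- model$layers[[l]]$W + vel$layer_W[[l]]
          model$layers[[l]]$b <- model$layers[[l]]$b + vel$layer_b[[l]]
        }
      }
    }
    loss[ep] <- tot / n
  }
  list(model = model, loss = loss)
}

# one-hot targets (multi-class) or scalar 0/1 (binary head)
label_targets <- function(labels, n_out) {
  if (n_out == 1L) {
    if (!all(labels %in% c(0, 1)))
      stop("binary-head labels must be 0/1")
    lapply(labels, function(l) as.numeric(l))
  } else {
    if (!all(labels %in% seq_len(n_out)))
      stop("labels must lie in 1..", n_out)
    lapply(labels, function(l) { t <- numeric(n_out); t[l] <- 1; t })
  }
}

#' Greedy pretraining of a CDBN on a labelled patch set
#'
#' Trains the CRBM layers greedily and layer-wise by sparsity-regularised
#' CD-1 (layer 2 on the pooled representations of layer 1), then trains
#' the fully connected head by gradient descent with momentum on the
#' cross-entropy of the logistic outputs, with the CRBM features fixed.
#'
#' @param dataset List with `patches` (list of patches) and `labels`
#'   (integers `1..n_out`), e.g. from [make_class_dataset()].
#' @param config Architecture config ([cdbn_preset()]).
#' @param crbm_epochs,head_epochs Training lengths for the CRBM stages and
#'   the head.
#' @param learning_rate,momentum,batch_size SGD settings shared by both
#'   stages.
#' @param sparsity_weight Sparsity penalty weight for the CRBM stages.
#' @param standardize Standardise patches before layer 1 (default TRUE).
#' @param seed Optional integer seed.
#' @return List: trained `model`, `crbm_traces` (per-layer training
#'   traces), `head_loss` (per-epoch), `train_accuracy`.
#' @export
cdbn_pretrain <- function(dataset, config = cdbn_preset("reduced"),
                          crbm_epochs = 50L, head_epochs = 100L,
                          learning_rate = 0.1, momentum = 0.5,
                          batch_size = 64L, sparsity_weight = 1000,
                          standardize = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- dataset$labels
  if (length(unique(labels)) < 2L)
    stop("pretraining needs at least two classes")
  model <- cdbn_build(config)
  x <- dataset$patches
  if (standardize) x <- lapply(x, standardize_patch)
  x <- lapply(x, as_visible, layer = model$layers[[1L]])
  traces <- vector("list", length(model$layers))
  for (l in seq_along(model$layers)) {
    fit <- crbm_train_layer(x, model$layers[[l]], epochs = crbm_epochs,
                            learning_rate = learning_rate,
                            momentum = momentum, batch_size = batch_size,
                            sparsity_weight = sparsity_weight)
    model$layers[[l]] <- fit$layer
    traces[[l]] <- fit$trace
    if (l < length(model$layers))
      x <- lapply(x, crbm_pooled_representation, layer = fit$layer)
  }
  # head training on fixed CRBM features
  flat <- ncol(model$fc_W)
  feats <- vapply(x, function(p)
    as.vector(crbm_pooled_representation(
      p, model$layers[[length(model$layers)]])),
    numeric(flat))
  # freeze a per-feature affine standardisation so the logistic head sees
  # O(1) inputs despite the sparse pooled activations
  model$feat_mean <- rowMeans(feats)
  model$feat_sd <- pmax(apply(feats, 1L, stats::sd), 1e-6)
  feats <- pmin(pmax((feats - model$feat_mean) / model$feat_sd, -4), 4)
  head <- train_head(model, feats, labels, epochs = head_epochs,
                     learning_rate = learning_rate, momentum = momentum,
                     batch_size = batch_size)
  model$fc_W <- head$fc_W; model$fc_b <- head$fc_b
  model$out_W <- head$out_W; model$out_b <- head$out_b
  pred <- apply(head$final_probs, 2L, which.max)
  model$provenance <- list(pretrained_on = "labelled patch set",
                           n_samples = length(labels),
                           crbm_epochs = crbm_epochs,
                           head_epochs = head_epochs)
  list(model = model, crbm_traces = traces, head_loss = head$loss,
       train_accuracy = mean(pred == labels))
}

# minibatch SGD with momentum for the FC head on cached features
# feats: D x N matrix, labels: 1..n_out
train_head <- function(model, feats, labels, epochs, learning_rate,
                       momentum, batch_size, weight_decay = 1e-3) {
  n <- ncol(feats)
  Y <- matrix(0, nrow = model$n_out, ncol = n)
  Y[cbind(labels, seq_len(n))] <- 1
  fc_W <- model$fc_W; fc_b <- model$fc_b
  out_W <- model$out_W; out_b <- model$out_b
  vW3 <- fc_W * 0; vb3 <- fc_b * 0; vW4 <- out_W * 0; vb4 <- out_b * 0
  loss <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      X <- feats[, idx, drop = FALSE]
      Yb <- Y[, idx, drop = FALSE]
      A3 <- logistic(sweep(fc_W %*% X, 1L, fc_b, "+"))
      A4 <- logistic(sweep(out_W %*% A3, 1L, out_b, "+"))
      tot <- tot + xent(A4, Yb)
      dZ4 <- A4 - Yb
      dA3 <- crossprod(out_W, dZ4)
      dZ3 <- dA3 * A3 * (1 - A3)
      m <- length(idx)
      vW4 <- momentum * vW4 -
        learning_rate * (tcrossprod(dZ4, A3) / m + weight_decay * out_W)
      vb4 <- momentum * vb4 - learning_rate / m * rowSums(dZ4)
      vW3 <- momentum * vW3 -
        learning_rate * (tcrossprod(dZ3, X) / m + weight_decay * fc_W)
      vb3 <- momentum * vb3 - learning_rate / m * rowSums(dZ3)
      out_W <- out_W + vW4; out_b <- out_b + vb4
      fc_W <- fc_W + vW3; fc_b <- fc_b + vb3
    }
    loss[ep] <- tot / n
  }
  A3 <- logistic(sweep(fc_W %*% feats, 1L, fc_b, "+"))
  A4 <- logistic(sweep(out_W %*% A3, 1L, out_b, "+"))
  list(fc_W = fc_W, fc_b = fc_b, out_W = out_W, out_b = out_b,
       loss = loss, final_probs = A4)
}

#' Transfer a pretrained CDBN to a new output head
#'
#' Preserves every CRBM and FC parameter bit-exactly and replaces the
#' output layer with a freshly initialised one of `n_out` units (one unit
#' for tracking: the foreground confidence).
#'
#' @param model A trained `cdbn_model`.
#' @param n_out Number of output units in the new head (>= 1).
#' @param init_sd Initialisation standard deviation of the new head.
#' @return The transferred `cdbn_model`.
#' @export
cdbn_transfer_output <- function(model, n_out = 1L, init_sd = 0.01) {
  if (n_out < 1L) stop("n_out must be >= 1")
  model$out_W <- matrix(rnorm(n_out * model$fc_units, sd = init_sd),
                        nrow = n_out)
  model$out_b <- numeric(n_out)
  model$n_out <- as.integer(n_out)
  model
}

#' Foreground confidence of a patch
#'
#' The logistic activation of the single output unit, used as the particle
#' filter's observation likelihood `p(y_t | x_t)`.
#'
#' @param model A transferred `cdbn_model` with `n_out = 1`.
#' @param v Standardised visible patch.
#' @return Scalar strictly inside (0,1).
#' @export
cdbn_confidence <- function(model, v) {
  if (model$n_out != 1L)
    stop("model has ", model$n_out,
         " output units; transfer it to a single-unit head first")
  out <- cdbn_forward(model, v)$output
  min(max(out, 1e-12), 1 - 1e-12)
}
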
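# Convolutional restricted Boltzmann machine with probabilistic max-pooling.
#
# Real-valued visible units v (n_V x n_V x channels), binary hidden units
# h^k (n_H x n_H per filter k), n_H = n_V - n_W + 1.  Hidden units are
# partitioned into C x C blocks B_a; at most one unit per block may be on,
# and the pooling unit p_a^k is on iff some unit in its block is.  The
# energy is
#
#   E(v,h) = 1/2 sum v^2 - sum_k sum_ij sum_rs h_ij^k W_rs^k v_{i+r-1,j+s-1}
#            - sum_k b_k sum_ij h_ij^k - c sum_ij v_ij
#
# (summed over channels), which yields a (C^2+1)-way softmax per block for
# the hidden conditionals and a unit-variance Gaussian for the visibles.

#' Construct a CRBM layer
#'
#' @param n_v Input side length (square input).
#' @param n_w Filter side length; hidden side is `n_v - n_w + 1`.
#' @param n_filters Number of convolution filters K.
#' @param channels Number of input channels.
#' @param pool Pooling block side C; the hidden side must be divisible by it.
#' @param sparsity_target Target mean activation of each hidden map, in (0,1).
#' @param init_sd Standard deviation of the zero-mean Gaussian filter
#'   initialisation; biases start at zero.
#' @return An object of class `crbm_layer`: filters `W` (n_w x n_w x
#'   channels x K), hidden biases `b` (length K), visible bias `c_bias`,
#'   and the geometry fields.
#' @export
new_crbm_layer <- function(n_v, n_w, n_filters, channels = 1L, pool = 2L,
                           sparsity_target = 0.003, init_sd = 0.01) {
  n_v <- as.integer(n_v); n_w <- as.integer(n_w); pool <- as.integer(pool)
  n_filters <- as.integer(n_filters); channels <- as.integer(channels)
  n_h <- n_v - n_w + 1L
  if (n_h < 1L) stop("filter side ", n_w, " exceeds input side ", n_v)
  if (n_h %% pool != 0L)
    stop("hidden side ", n_h, " is not divisible by pooling block size ", pool)
  if (n_filters < 1L) stop("need at least one filter")
  if (sparsity_target <= 0 || sparsity_target >= 1)
    stop("sparsity_target must lie in (0,1)")
  W <- array(rnorm(n_w * n_w * channels * n_filters, sd = init_sd),
             dim = c(n_w, n_w, channels, n_filters))
  structure(list(
    W = W, b = numeric(n_filters), c_bias = 0,
    n_v = as.integer(n_v), n_w = as.integer(n_w), n_h = n_h,
    channels = as.integer(channels), n_filters = as.integer(n_filters),
    pool = as.integer(pool), n_p = as.integer(n_h %/% pool),
    sparsity_target = sparsity_target
  ), class = "crbm_layer")
}

#' @export
print.crbm_layer <- function(x, ...) {
  cat(sprintf(
    "CRBM layer: %d filters %dx%dx%d, input %dx%dx%d -> hidden %d -> pooled %d (C=%d)\n",
    x$n_filters, x$n_w, x$n_w, x$channels, x$n_v, x$n_v, x$channels,
    x$n_h, x$n_p, x$pool))
  cat(sprintf("  sparsity target %.4g, %d parameters\n",
              x$sparsity_target, length(x$W) + length(x$b) + 1L))
  invisible(x)
}

# coerce a patch to the n_v x n_v x channels array the layer expects
as_visible <- function(v, layer) {
  if (is.matrix(v)) v <- array(v, dim = c(dim(v), 1L))
  d <- dim(v)
  if (length(d) != 3L || d[1] != layer$n_v || d[2] != layer$n_v ||
      d[3] != layer$channels)
    stop("visible patch has shape ", paste(d, collapse = "x"),
         ", layer expects ", layer$n_v, "x", layer$n_v, "x", layer$channels)
  if (!all(is.finite(v))) stop("visible patch contains non-finite values")
  v
}

# reshape an n_h x n_h x K array into a (C^2) x (n_blocks) matrix whose
# columns are pooling blocks (blocks ordered column-major within each map)
block_matrix <- function(a, C) {
  d <- dim(a); np <- d[1] %/% C; K <- d[3]
  dim(a) <- c(C, np, C, np, K)
  a <- aperm(a, c(1L, 3L, 2L, 4L, 5L))
  dim(a) <- c(C * C, np * np * K)
  a
}

# inverse of block_matrix
unblock_matrix <- function(m, C, np, K) {
  dim(m) <- c(C, C, np, np, K)
  m <- aperm(m, c(1L, 3L, 2L, 4L, 5L))
  dim(m) <- c(C * np, C * np, K)
  m
}

# replicate each pooling-block value over its C x C block
expand_blocks <- function(p, C) {
  d <- dim(p)
  p[rep(seq_len(d[1]), each = C), rep(seq_len(d[2]), each = C), , drop = FALSE]
}

#' CRBM energy
#'
#' Evaluates the joint energy E(v, h) of a visible patch and a hidden state
#' satisfying the at-most-one-per-block pooling constraint.
#'
#' @param v Visible patch, `n_v x n_v` matrix or `n_v x n_v x channels` array.
#' @param h Hidden state as returned by [crbm_sample_hidden()], or a binary
#'   `n_h x n_h x K` array.
#' @param layer A `crbm_layer`.
#' @return The scalar energy.
#' @export
crbm_energy <- function(v, h, layer) {
  v <- as_visible(v, layer)
  units <- if (is.list(h)) h$units else h
  if (!all(dim(units) == c(layer$n_h, layer$n_h, layer$n_filters)))
    stop("hidden state has wrong shape")
  bm <- block_matrix(units, layer$pool)
  if (any(colSums(bm) > 1))
    stop("hidden state violates the pooling block constraint")
  Iw <- cpp_corr_valid(v, layer$W)          # (W-tilde *_v v), no bias
  per_map <- apply(units, 3L, sum)
  0.5 * sum(v^2) - sum(units * Iw) - sum(layer$b * per_map) -
    layer$c_bias * sum(v)
}

# stable block softmax: given pre-activations I (n_h x n_h x K) return
# P(h_ij = 1 | v) and P(p_a = 0 | v)
block_softmax <- function(I, C) {
  d <- dim(I); np <- d[1] %/% C; K <- d[3]
  m <- block_matrix(I, C)
  nr <- nrow(m); nc <- ncol(m)
  mx <- m[1L, ]
  if (nr > 1L) for (i in 2:nr) mx <- pmax(mx, m[i, ])
  mx <- pmax(mx, 0)
  e <- exp(m - rep(mx, each = nr))
  off <- exp(-mx)
  denom <- off + .colSums(e, nr, nc)
  probs <- e / rep(denom, each = nr)
  pool_off <- off / denom
  list(unit_probs = unblock_matrix(probs, C, np, K),
       pool_off = array(pool_off, dim = c(np, np, K)))
}

# sum over each map of an n_h x n_h x K array
map_sums <- function(a) {
  d <- dim(a)
  .colSums(a, d[1] * d[2], d[3])
}

#' Hidden-unit conditionals given the visibles
#'
#' Computes, for every filter map and pooling block, the block-softmax
#' conditionals `P(h_ij^k = 1 | v)` and `P(p_a^k = 0 | v)` from the
#' pre-activations `I(h_ij^k) = (W~^k *_v v)_ij + b_k`.  Within every block
#' the unit probabilities and the pool-off probability sum to one.
#'
#' @inheritParams crbm_energy
#' @return List with `unit_probs` (n_h x n_h x K) and `pool_off`
#'   (n_h/C x n_h/C x K).
#' @export
crbm_hidden_conditionals <- function(v, layer) {
  v <- as_visible(v, layer)
  I <- cpp_corr_valid(v, layer$W)
  cpp_block_softmax(I, layer$b, layer$pool)
}

#' Sample a hidden state from block-softmax conditionals
#'
#' Draws, independently per pooling block, one outcome of the
#' `(C^2 + 1)`-way categorical over the block's units and the all-off state.
#' The returned state always satisfies the pooling constraint.
#'
#' @param cond Conditionals from [crbm_hidden_conditionals()].
#' @param layer The `crbm_layer` they were computed for.
#' @return List of class `crbm_hidden` with binary arrays `units`
#'   (n_h x n_h x K) and `pool` (n_h/C x n_h/C x K).
#' @export
crbm_sample_hidden <- function(cond, layer) {
  C <- layer$pool; np <- layer$n_p; K <- layer$n_filters
  pm <- block_matrix(cond$unit_probs, C)      # C^2 x n_blocks
  nb <- ncol(pm); nr <- nrow(pm)
  u <- runif(nb)
  cum <- pm
  if (nr > 1L) for (i in 2:nr) cum[i, ] <- cum[i, ] + cum[i - 1L, ]
  pick <- .colSums(cum < rep(u, each = nr), nr, nb) + 1L
  units <- matrix(0, nrow = nr, ncol = nb)
  on <- which(pick <= nr)
  units[cbind(pick[on], on)] <- 1
  # pooling unit is on iff any unit in its block is on, i.e. pick <= C^2
  pool <- array(as.numeric(pick <= nr), dim = c(np, np, K))
  units <- unblock_matrix(units, C, np, K)
  structure(list(units = units, pool = pool), class = "crbm_hidden")
}

#' Visible-unit conditional means given a hidden state
#'
#' Returns the mean of the unit-variance Gaussian conditional
#' `P(v | h) = N(sum_k (W^k *_f h^k) + c, 1)` (full convolution).
#'
#' @inheritParams crbm_sample_hidden
#' @param h Hidden state (`crbm_hidden` or a binary/real n_h x n_h x K array).
#' @return Array `n_v x n_v x channels` of conditional means.
#' @export
crbm_visible_conditionals <- function(h, layer) {
  units <- if (is.list(h)) h$units else h
  if (is.matrix(units)) units <- array(units, dim = c(dim(units), 1L))
  cpp_conv_full(units, layer$W) + layer$c_bias
}

#' Deterministic pooled representation of a patch
#'
#' The pooling-unit on-probabilities `P(p_a^k = 1 | v) = 1 - P(p_a^k = 0 | v)`
#' used as the deterministic activation passed to the next layer.
#'
#' @inheritParams crbm_energy
#' @return Array `(n_h/C) x (n_h/C) x K` with values in (0,1).
#' @export
crbm_pooled_representation <- function(v, layer) {
  1 - crbm_hidden_conditionals(v, layer)$pool_off
}

#' One-step contrastive-divergence gradient with sparsity penalty
#'
#' Computes CD-1 increments for the filters, hidden biases and visible bias
#' on a minibatch: positive-phase statistics from the data conditionals,
#' negative phase from one Gibbs reconstruction (sampled hidden state,
#' Gaussian mean reconstruction).  A squared-error sparsity penalty
#' `-lambda * (target - q_k)^2` on each map's mean activation `q_k` is
#' differentiated exactly through the block softmax and added.  Likelihood
#' increments are averaged per hidden unit and per patch.
#'
#' @param batch List of visible patches.
#' @param layer A `crbm_layer`.
#' @param sparsity_weight Penalty weight lambda (>= 0).
#' @return List with increments `dW`, `db`, `dc`, plus diagnostics
#'   `recon_error` (mean squared reconstruction error) and `mean_activation`
#'   (per-map data-phase mean activation).
#' @export
crbm_cd1_gradient <- function(batch, layer, sparsity_weight = 0) {
  if (length(batch) == 0L) stop("empty batch")
  K <- layer$n_filters
  nunit <- layer$n_h^2
  B <- length(batch)
  dW <- array(0, dim = dim(layer$W)); db <- numeric(K); dc <- 0
  recon_err <- 0
  qsum <- numeric(K)
  pos <- vector("list", B)   # cached data-phase conditionals for sparsity pass
  vs <- vector("list", B)
  for (i in seq_len(B)) {
    v <- as_visible(batch[[i]], layer)
    cond <- crbm_hidden_conditionals(v, layer)
    hs <- crbm_sample_hidden(cond, layer)
    vneg <- crbm_visible_conditionals(hs, layer)
    cneg <- crbm_hidden_conditionals(vneg, layer)
    dW <- dW + cpp_grad_filters(v, cond$unit_probs) -
               cpp_grad_filters(vneg, cneg$unit_probs)
    db <- db + map_sums(cond$unit_probs) - map_sums(cneg$unit_probs)
    dc <- dc + sum(v) - sum(vneg)
    recon_err <- recon_err + mean((v - vneg)^2)
    qsum <- qsum + map_sums(cond$unit_probs) / nunit
    pos[[i]] <- cond; vs[[i]] <- v
  }
  scale <- 1 / (B * nunit)
  dW <- dW * scale; db <- db * scale; dc <- dc * scale
  q <- qsum / B
  if (sparsity_weight > 0) {
    # d/dtheta of -lambda (p - q_k)^2 = 2 lambda (p - q_k) dq_k/dtheta with
    # dq_k/dI_u = prob_u * pool_off(block) / (B * nunit)
    coef <- 2 * sparsity_weight * (layer$sparsity_target - q) / (B * nunit)
    for (i in seq_len(B)) {
      g <- cpp_block_expand_mult(pos[[i]]$unit_probs, pos[[i]]$pool_off,
                                 layer$pool)
      g <- sweep(g, 3L, coef, "*")
      dW <- dW + cpp_grad_filters(vs[[i]], g)
      db <- db + map_sums(g)
    }
  }
  list(dW = dW, db = db, dc = dc,
       recon_error = recon_err / B, mean_activation = q)
}

#' Train one CRBM layer by minibatch CD-1 with momentum
#'
#' @param data List of visible patches (all the same shape).
#' @param layer Initial `crbm_layer` (see [new_crbm_layer()]).
#' @param epochs Number of passes over the data.
#' @param learning_rate,momentum SGD-with-momentum settings.
#' @param batch_size Minibatch size.
#' @param sparsity_weight Weight of the mean-activation sparsity penalty.
#' @param shuffle Reshuffle the data each epoch.
#' @return List with the trained `layer` and a `trace` data frame
#'   (per-epoch mean reconstruction error and mean hidden activation),
#'   carrying the hyperparameters as attributes.
#' @export
crbm_train_layer <- function(data, layer, epochs = 50L, learning_rate = 0.1,
                             momentum = 0.5, batch_size = 64L,
                             sparsity_weight = 1000, shuffle = TRUE) {
  stopifnot(length(data) >= 1L)
  vW <- array(0, dim = dim(layer$W)); vb <- numeric(layer$n_filters); vc <- 0
  trace <- data.frame(epoch = integer(0), recon_error = numeric(0),
                      mean_activation = numeric(0))
  n <- length(data)
  for (ep in seq_len(epochs)) {
    ord <- if (shuffle) sample.int(n) else seq_len(n)
    err <- 0; act <- 0; nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      g <- crbm_cd1_gradient(data[idx], layer, sparsity_weight)
      vW <- momentum * vW + learning_rate * g$dW
      vb <- momentum * vb + learning_rate * g$db
      vc <- momentum * vc + learning_rate * g$dc
      layer$W <- layer$W + vW
      layer$b <- layer$b + vb
      layer$c_bias <- layer$c_bias + vc
      if (!all(is.finite(layer$W)) || !all(is.finite(layer$b)))
        stop("CRBM training diverged (non-finite parameters) at epoch ", ep)
      err <- err + g$recon_error; act <- act + mean(g$mean_activation)
      nb <- nb + 1L
    }
    trace <- rbind(trace, data.frame(
      epoch = ep, recon_error = err / nb, mean_activation = act / nb))
  }
  attr(trace, "hyperparameters") <- list(
    learning_rate = learning_rate, momentum = momentum, epochs = epochs,
    batch_size = batch_size, sparsity_weight = sparsity_weight)
  list(layer = layer, trace = trace)
}

#' Mean hidden activation of a layer over a patch set
#'
#' @param data List of visible patches.
#' @param layer A `crbm_layer`.
#' @return Mean of `P(h = 1 | v)` over all units, maps and patches.
#' @export
crbm_mean_activation <- function(data, layer) {
  mean(vapply(data, function(v)
    mean(crbm_hidden_conditionals(v, layer)$unit_probs), numeric(1)))
}

#' Standardise a patch to zero mean, unit variance
#'
#' Per-patch standardisation applied to every patch before it enters the
#' first CRBM layer (the energy assumes unit-variance Gaussian visibles).
#' Constant patches map to all zeros.
#'
#' @param v Matrix or array patch.
#' @return Standardised array with attributes `norm_mean` and `norm_sd`.
#' @export
standardize_patch <- function(v) {
  if (is.matrix(v)) v <- array(v, dim = c(dim(v), 1L))
  m <- mean(v); s <- stats::sd(as.vector(v))
  out <- if (is.na(s) || s < 1e-8) array(0, dim = dim(v)) else (v - m) / s
  attr(out, "norm_mean") <- m
  attr(out, "norm_sd") <- if (is.na(s)) 0 else s
  out
}
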
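# Independent oracles used by the tests: naive loop-based energy and
# convolutions, exhaustive enumeration of the Boltzmann distribution on
# tiny CRBMs, and a reference bilinear resampler.  These deliberately
# share no code with the package internals.

# energy by direct triple-loop summation of the defining formula
naive_energy <- function(v, units, layer) {
  if (is.matrix(v)) v <- array(v, dim = c(dim(v), 1L))
  nW <- layer$n_w; nH <- layer$n_h; K <- layer$n_filters
  acc <- 0.5 * sum(v^2) - layer$c_bias * sum(v)
  for (k in seq_len(K)) {
    for (i in seq_len(nH)) for (j in seq_len(nH)) {
      if (units[i, j, k] == 0) next
      s <- 0
      for (ch in seq_len(layer$channels))
        for (r in seq_len(nW)) for (ss in seq_len(nW))
          s <- s + layer$W[r, ss, ch, k] * v[i + r - 1, j + ss - 1, ch]
      acc <- acc - s - layer$b[k]
    }
  }
  acc
}

# all hidden configurations satisfying the pooling constraint, as a list
# of binary n_h x n_h x K arrays (every block picks one unit or none)
enumerate_hidden <- function(layer) {
  C <- layer$pool; np <- layer$n_p; K <- layer$n_filters
  n_blocks <- np * np * K
  choices <- expand.grid(rep(list(0:(C * C)), n_blocks))
  lapply(seq_len(nrow(choices)), function(r) {
    units <- array(0, dim = c(layer$n_h, layer$n_h, K))
    bl <- 0L
    for (k in seq_len(K)) for (bj in seq_len(np)) for (bi in seq_len(np)) {
      bl <- bl + 1L
      pick <- choices[r, bl]
      if (pick > 0) {
        # unit index within the C x C block, column-major
        ri <- (pick - 1) %% C + 1
        ci <- (pick - 1) %/% C + 1
        units[(bi - 1) * C + ri, (bj - 1) * C + ci, k] <- 1
      }
    }
    units
  })
}

# exact conditionals P(h_ij = 1 | v), P(p_a = 0 | v) by enumerating the
# Boltzmann distribution over all valid hidden configurations
enumerate_conditionals <- function(v, layer) {
  configs <- enumerate_hidden(layer)
  logw <- vapply(configs, function(u) -naive_energy(v, u, layer), numeric(1))
  w <- exp(logw - max(logw)); w <- w / sum(w)
  np <- layer$n_p; K <- layer$n_filters
  unit_probs <- array(0, dim = c(layer$n_h, layer$n_h, K))
  pool_off <- array(0, dim = c(np, np, K))
  C <- layer$pool
  for (i in seq_along(configs)) {
    unit_probs <- unit_probs + w[i] * configs[[i]]
    for (k in seq_len(K)) for (bj in seq_len(np)) for (bi in seq_len(np)) {
      blk <- configs[[i]][(bi - 1) * C + seq_len(C),
                          (bj - 1) * C + seq_len(C), k]
      if (sum(blk) == 0) pool_off[bi, bj, k] <- pool_off[bi, bj, k] + w[i]
    }
  }
  list(unit_probs = unit_probs, pool_off = pool_off)
}

# log p(v) up to an additive constant independent of the parameters:
# log sum_h exp(-E(v,h)) - log sum_h exp(b.sum(h) + ||a(h)||^2 / 2)
# where a(h) is the Gaussian conditional mean of the visibles given h
naive_loglik <- function(v, layer) {
  configs <- enumerate_hidden(layer)
  le <- vapply(configs, function(u) -naive_energy(v, u, layer), numeric(1))
  lz <- vapply(configs, function(u) {
    a <- naive_full_conv(u, layer) + layer$c_bias
    sum(layer$b * apply(u, 3, sum)) + 0.5 * sum(a^2)
  }, numeric(1))
  lse <- function(x) max(x) + log(sum(exp(x - max(x))))
  lse(le) - lse(lz)
}

# full convolution sum_k W^k *_f h^k by direct loops
naive_full_conv <- function(units, layer) {
  nW <- layer$n_w; nH <- layer$n_h
  out <- array(0, dim = c(layer$n_v, layer$n_v, layer$channels))
  for (k in seq_len(layer$n_filters))
    for (ch in seq_len(layer$channels))
      for (i in seq_len(nH)) for (j in seq_len(nH)) {
        if (units[i, j, k] == 0) next
        for (r in seq_len(nW)) for (s in seq_len(nW))
          out[i + r - 1, j + s - 1, ch] <-
            out[i + r - 1, j + s - 1, ch] + layer$W[r, s, ch, k]
      }
  out
}

# reference bilinear resampler: samples the centres of `side` cells over
# the box [x1,x2) x [y1,y2) (continuous 0-based frame coordinates)
naive_bilinear <- function(frame, x1, y1, x2, y2, side) {
  H <- nrow(frame); W <- ncol(frame)
  out <- matrix(0, side, side)
  for (u in seq_len(side)) for (vv in seq_len(side)) {
    sx <- min(max(x1 + (u - 0.5) * (x2 - x1) / side + 0.5, 1), W)
    sy <- min(max(y1 + (vv - 0.5) * (y2 - y1) / side + 0.5, 1), H)
    ix <- min(floor(sx), W - 1); iy <- min(floor(sy), H - 1)
    fx <- sx - ix; fy <- sy - iy
    out[vv, u] <- frame[iy, ix] * (1 - fy) * (1 - fx) +
      frame[iy + 1, ix] * fy * (1 - fx) +
      frame[iy, ix + 1] * (1 - fy) * fx +
      frame[iy + 1, ix + 1] * fy * fx
  }
  out
}
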
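#include <Rcpp.h>
using namespace Rcpp;

// Multi-channel valid cross-correlation.
// v: H x W x Cin, f: nW x nW x Cin x K  ->  out: nH x nHc x K
// out(i,j,k) = sum_c sum_{r,s} f(r,s,c,k) * v(i+r-1, j+s-1, c)
// This is the hidden pre-activation I(h^k) of the CRBM (the energy pairs
// h_ij with v_{i+r-1,j+s-1}, i.e. correlation with the unflipped filter).
// [[Rcpp::export]]
NumericVector cpp_corr_valid(NumericVector v, NumericVector f) {
  IntegerVector dv = v.attr("dim");
  IntegerVector df = f.attr("dim");
  const int H = dv[0], W = dv[1], C = dv[2];
  const int nW = df[0], nWc = df[1], Cf = df[2], K = df[3];
  if (Cf != C) stop("channel mismatch: input has %d, filters expect %d", C, Cf);
  const int nH = H - nW + 1, nHc = W - nWc + 1;
  if (nH < 1 || nHc < 1) stop("filter larger than input");
  NumericVector out(nH * nHc * K);
  out.attr("dim") = IntegerVector::create(nH, nHc, K);
  const double *pv = v.begin(), *pf = f.begin();
  double *po = out.begin();
  for (int k = 0; k < K; ++k) {
    for (int c = 0; c < C; ++c) {
      const double *vc = pv + (size_t)c * H * W;
      const double *fc = pf + ((size_t)k * C + c) * nW * nWc;
      for (int j = 0; j < nHc; ++j) {
        for (int i = 0; i < nH; ++i) {
          double acc = 0.0;
          for (int s = 0; s < nWc; ++s) {
            const double *vcol = vc + (size_t)(j + s) * H + i;
            const double *fcol = fc + (size_t)s * nW;
            for (int r = 0; r < nW; ++r) acc += fcol[r] * vcol[r];
          }
          po[(size_t)k * nH * nHc + (size_t)j * nH + i] += acc;
        }
      }
    }
  }
  return out;
}

// Multi-map full convolution: h: nH x nHc x K, f: nW x nW x Cin x K
//  ->  out: (nH+nW-1) x (nHc+nW-1) x Cin
// out(u,t,c) = sum_k sum_{r,s} f(r,s,c,k) * h(u-r+1, t-s+1, k)
// Used for the Gaussian visible mean sum_k W^k *_f h^k and for
// backpropagating hidden-layer gradients to the layer input.
// [[Rcpp::export]]
NumericVector cpp_conv_full(NumericVector h, NumericVector f) {
  IntegerVector dh = h.attr("dim");
  IntegerVector df = f.attr("dim");
  const int nH = dh[0], nHc = dh[1], K = dh[2];
  const int nW = df[0], nWc = df[1], C = df[2], Kf = df[3];
  if (Kf != K) stop("map mismatch: hidden has %d maps, filters have %d", K, Kf);
  const int H = nH + nW - 1, W = nHc + nWc - 1;
  NumericVector out(H * W * C);
  out.attr("dim") = IntegerVector::create(H, W, C);
  const double *ph = h.begin(), *pf = f.begin();
  double *po = out.begin();
  for (int k = 0; k < K; ++k) {
    const double *hk = ph + (size_t)k * nH * nHc;
    for (int c = 0; c < C; ++c) {
      const double *fc = pf + ((size_t)k * C + c) * nW * nWc;
      double *oc = po + (size_t)c * H * W;
      for (int j = 0; j < nHc; ++j) {
        for (int i = 0; i < nH; ++i) {
          const double hv = hk[(size_t)j * nH + i];
          if (hv == 0.0) continue;
          for (int s = 0; s < nWc; ++s) {
            double *ocol = oc + (size_t)(j + s) * H + i;
            const double *fcol = fc + (size_t)s * nW;
            for (int r = 0; r < nW; ++r) ocol[r] += hv * fcol[r];
          }
        }
      }
    }
  }
  return out;
}

// Filter-gradient accumulation: v: H x W x Cin, g: nH x nHc x K
//  ->  grad: nW x nW x Cin x K with nW = H - nH + 1
// grad(r,s,c,k) = sum_{i,j} g(i,j,k) * v(i+r-1, j+s-1, c)
// The positive/negative phase statistics of CD and the filter gradient of
// the discriminative backward pass are both this correlation.
// [[Rcpp::export]]
NumericVector cpp_grad_filters(NumericVector v, NumericVector g) {
  IntegerVector dv = v.attr("dim");
  IntegerVector dg = g.attr("dim");
  const int H = dv[0], W = dv[1], C = dv[2];
  const int nH = dg[0], nHc = dg[1], K = dg[2];
  const int nW = H - nH + 1, nWc = W - nHc + 1;
  if (nW < 1 || nWc < 1) stop("gradient map larger than input");
  NumericVector out(nW * nWc * C * K);
  out.attr("dim") = IntegerVector::create(nW, nWc, C, K);
  const double *pv = v.begin(), *pg = g.begin();
  double *po = out.begin();
  for (int k = 0; k < K; ++k) {
    const double *gk = pg + (size_t)k * nH * nHc;
    for (int c = 0; c < C; ++c) {
      const double *vc = pv + (size_t)c * H * W;
      double *oc = po + ((size_t)k * C + c) * nW * nWc;
      for (int j = 0; j < nHc; ++j) {
        for (int i = 0; i < nH; ++i) {
          const double gv = gk[(size_t)j * nH + i];
          if (gv == 0.0) continue;
          for (int s = 0; s < nWc; ++s) {
            const double *vcol = vc + (size_t)(j + s) * H + i;
            double *ocol = oc + (size_t)s * nW;
            for (int r = 0; r < nW; ++r) ocol[r] += gv * vcol[r];
          }
        }
      }
    }
  }
  return out;
}

// Block softmax over C x C pooling blocks with per-map bias.
// I: nH x nH x K pre-activations (without bias), b: length-K biases.
// Returns probs (nH x nH x K) and pool_off (nP x nP x K) with
// probs = exp(I+b)/(1 + sum_block exp(I+b)), pool_off = 1/(1 + sum).
// Stable under a constant shift within each block (max-subtraction).
// [[Rcpp::export]]
List cpp_block_softmax(NumericVector I, NumericVector b, int C) {
  IntegerVector di = I.attr("dim");
  const int nH = di[0], nHc = di[1], K = di[2];
  const int nP = nH / C, nPc = nHc / C;
  NumericVector probs(nH * nHc * K);
  probs.attr("dim") = IntegerVector::create(nH, nHc, K);
  NumericVector poff(nP * nPc * K);
  poff.attr("dim") = IntegerVector::create(nP, nPc, K);
  const double *pi = I.begin();
  double *pp = probs.begin(), *po = poff.begin();
  for (int k = 0; k < K; ++k) {
    const double bk = b[k];
    const double *Ik = pi + (size_t)k * nH * nHc;
    double *Pk = pp + (size_t)k * nH * nHc;
    double *Ok = po + (size_t)k * nP * nPc;
    for (int bj = 0; bj < nPc; ++bj) {
      for (int bi = 0; bi < nP; ++bi) {
        double mx = 0.0;
        for (int s = 0; s < C; ++s)
          for (int r = 0; r < C; ++r) {
            const double v = Ik[(size_t)(bj * C + s) * nH + bi * C + r] + bk;
            if (v > mx) mx = v;
          }
        double denom = std::exp(-mx);
        for (int s = 0; s < C; ++s)
          for (int r = 0; r < C; ++r)
            denom += std::exp(
              Ik[(size_t)(bj * C + s) * nH + bi * C + r] + bk - mx);
        for (int s = 0; s < C; ++s)
          for (int r = 0; r < C; ++r) {
            const size_t ix = (size_t)(bj * C + s) * nH + bi * C + r;
            Pk[ix] = std::exp(Ik[ix] + bk - mx) / denom;
          }
        Ok[(size_t)bj * nP + bi] = std::exp(-mx) / denom;
      }
    }
  }
  return List::create(_["unit_probs"] = probs, _["pool_off"] = poff);
}

// Elementwise multiply of a hidden-shaped array by pooling-block values:
// out(i,j,k) = a(i,j,k) * blockvals(floor(i/C), floor(j/C), k).
// [[Rcpp::export]]
NumericVector cpp_block_expand_mult(NumericVector a, NumericVector bv,
                                    int C) {
  IntegerVector da = a.attr("dim");
  const int nH = da[0], nHc = da[1], K = da[2];
  const int nP = nH / C, nPc = nHc / C;
  NumericVector out(nH * nHc * K);
  out.attr("dim") = IntegerVector::create(nH, nHc, K);
  const double *pa = a.begin(), *pb = bv.begin();
  double *po = out.begin();
  for (int k = 0; k < K; ++k) {
    const double *bk = pb + (size_t)k * nP * nPc;
    for (int j = 0; j < nHc; ++j) {
      const double *bcol = bk + (size_t)(j / C) * nP;
      const size_t off = (size_t)k * nH * nHc + (size_t)j * nH;
      for (int i = 0; i < nH; ++i)
        po[off + i] = pa[off + i] * bcol[i / C];
    }
  }
  return out;
}
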
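#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Hot inner kernels for the conv backbone and the augmentation warp.
// Feature-map layout everywhere: one column per batch item, rows are a
// column-major (row, col, channel) plane stack, i.e. index r + (c-1)*H +
// (ch-1)*H*W with 1-based r, c.

// Gather im2col patches. Xp: padded batch (Hp*Wp*C x B). idx: 0-based
// indices into one padded image, ordered kernel-position-fastest then
// output-position (length KKC*P). Returns (KKC x P*B); column p + b*P is
// window p of batch item b.
// [[Rcpp::export]]
arma::mat nn_im2col(const arma::mat& Xp, const Rcpp::IntegerVector& idx, int KKC, int P) {
  const int B = Xp.n_cols;
  const std::size_t n = idx.size();
  const int* ix = idx.begin();
  arma::mat out(KKC, (std::size_t)P * B);
  for (int b = 0; b < B; ++b) {
    const double* src = Xp.colptr(b);
    double* dst = out.colptr((std::size_t)b * P);
    for (std::size_t j = 0; j < n; ++j) {
      const int k = ix[j];
      dst[j] = k >= 0 ? src[k] : 0.0;
    }
  }
  return out;
}

// Scatter-add transpose of nn_im2col. dXcol: (KKC x P*B). Returns (M x B)
// padded-image gradients.
// [[Rcpp::export]]
arma::mat nn_col2im(const arma::mat& dXcol, const Rcpp::IntegerVector& idx, int M, int P) {
  const std::size_t n = idx.size();
  const int* ix = idx.begin();
  const std::size_t B = dXcol.n_cols / (std::size_t)P;
  arma::mat out(M, B, arma::fill::zeros);
  for (std::size_t b = 0; b < B; ++b) {
    double* dst = out.colptr(b);
    const double* src = dXcol.colptr(b * (std::size_t)P);
    for (std::size_t j = 0; j < n; ++j) {
      const int k = ix[j];
      if (k >= 0) dst[k] += src[j];
    }
  }
  return out;
}

// Batched inverse-mapping bilinear affine warp with border clamping.
// X: (H*W x B) single-channel images. A: (B x 6) rows [a11 a12 a21 a22 ty tx].
// For output pixel (r, c), centered coords v = r - (Ho+1)/2, u = c - (Wo+1)/2:
//   source row = a11*v + a12*u + ty,  source col = a21*v + a22*u + tx.
// [[Rcpp::export]]
arma::mat nn_warp(const arma::mat& X, int H, int W, const arma::mat& A,
                  int Ho, int Wo) {
  const int B = X.n_cols;
  arma::mat out((std::size_t)Ho * Wo, B);
  const double cv = (Ho + 1) / 2.0, cu = (Wo + 1) / 2.0;
  for (int b = 0; b < B; ++b) {
    const double* src = X.colptr(b);
    double* dst = out.colptr(b);
    const double a11 = A(b, 0), a12 = A(b, 1), a21 = A(b, 2), a22 = A(b, 3);
    const double ty = A(b, 4), tx = A(b, 5);
    std::size_t q = 0;
    for (int c = 0; c < Wo; ++c) {
      const double u = (c + 1) - cu;
      for (int r = 0; r < Ho; ++r, ++q) {
        const double v = (r + 1) - cv;
        double sr = a11 * v + a12 * u + ty;
        double sc = a21 * v + a22 * u + tx;
        if (sr < 1.0) sr = 1.0; else if (sr > H) sr = H;
        if (sc < 1.0) sc = 1.0; else if (sc > W) sc = W;
        int r0 = (int)std::floor(sr); if (r0 > H - 1) r0 = H - 1;
        int c0 = (int)std::floor(sc); if (c0 > W - 1) c0 = W - 1;
        const double fr = sr - r0, fc = sc - c0;
        const double* p00 = src + (r0 - 1) + (std::size_t)(c0 - 1) * H;
        const double v00 = p00[0], v10 = p00[1];
        const double v01 = p00[H], v11 = p00[H + 1];
        dst[q] = (1 - fr) * ((1 - fc) * v00 + fc * v01) +
                 fr * ((1 - fc) * v10 + fc * v11);
      }
    }
  }
  return out;
}

// Batch-norm forward fused with the ReLU: out = max(gamma*(Z-mu)*inv + beta, 0)
// with batch statistics when train, supplied running statistics otherwise.
// [[Rcpp::export]]
Rcpp::List nn_bn_relu_fwd(const arma::mat& Z, const arma::vec& gamma,
                          const arma::vec& beta, bool train,
                          const arma::vec& run_mean, const arma::vec& run_var,
                          double eps) {
  const arma::uword n = Z.n_rows, C = Z.n_cols;
  arma::vec mu(C), var(C);
  if (train) {
    for (arma::uword c = 0; c < C; ++c) {
      const double* z = Z.colptr(c);
      double s = 0, s2 = 0;
      for (arma::uword i = 0; i < n; ++i) { s += z[i]; s2 += z[i] * z[i]; }
      mu[c] = s / n;
      var[c] = s2 / n - mu[c] * mu[c];
    }
  } else {
    mu = run_mean; var = run_var;
  }
  arma::mat out(n, C);
  for (arma::uword c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    const double a = gamma[c] * inv, b = beta[c] - mu[c] * a;
    const double* z = Z.colptr(c);
    double* o = out.colptr(c);
    for (arma::uword i = 0; i < n; ++i) {
      const double v = a * z[i] + b;
      o[i] = v > 0 ? v : 0;
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out, Rcpp::Named("mu") = mu,
                            Rcpp::Named("var") = var);
}

// Backward of (batch-norm -> ReLU). dA: gradient wrt post-ReLU output;
// out: the forward output (its zeros give the ReLU mask); Z, mu, var the
// forward inputs/statistics. Returns dZ, dgamma, dbeta.
// [[Rcpp::export]]
Rcpp::List nn_bn_relu_bwd(const arma::mat& dA, const arma::mat& out,
                          const arma::mat& Z, const arma::vec& mu,
                          const arma::vec& var, const arma::vec& gamma,
                          bool train, double eps) {
  const arma::uword n = Z.n_rows, C = Z.n_cols;
  arma::mat dZ(n, C);
  arma::vec dgamma(C), dbeta(C);
  for (arma::uword c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    const double* da = dA.colptr(c);
    const double* o = out.colptr(c);
    const double* z = Z.colptr(c);
    double* dz = dZ.colptr(c);
    double sg = 0, sb = 0, s1 = 0, s2 = 0;
    for (arma::uword i = 0; i < n; ++i) {
      const double g = o[i] > 0 ? da[i] : 0.0;   // ReLU mask
      const double xhat = (z[i] - mu[c]) * inv;
      sg += g * xhat;
      sb += g;
      dz[i] = g;                                  // stash masked grad
    }
    dgamma[c] = sg; dbeta[c] = sb;
    if (train) {
      s1 = gamma[c] * sb / n;
      s2 = gamma[c] * sg / n;
      for (arma::uword i = 0; i < n; ++i) {
        const double xhat = (z[i] - mu[c]) * inv;
        dz[i] = inv * (gamma[c] * dz[i] - s1 - xhat * s2);
      }
    } else {
      const double a = gamma[c] * inv;
      for (arma::uword i = 0; i < n; ++i) dz[i] *= a;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dZ") = dZ,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}


// (P*B x C) conv-output layout -> (P*C x B) plane layout for the next layer.
// [[Rcpp::export]]
arma::mat nn_to_planes(const arma::mat& X, int P, int B, int C) {
  arma::mat out((std::size_t)P * C, B);
  for (int c = 0; c < C; ++c) {
    const double* src = X.colptr(c);
    for (int b = 0; b < B; ++b) {
      std::memcpy(out.colptr(b) + (std::size_t)c * P,
                  src + (std::size_t)b * P, sizeof(double) * P);
    }
  }
  return out;
}

// inverse of nn_to_planes
// [[Rcpp::export]]
arma::mat nn_from_planes(const arma::mat& X, int P, int B, int C) {
  arma::mat out((std::size_t)P * B, C);
  for (int c = 0; c < C; ++c) {
    double* dst = out.colptr(c);
    for (int b = 0; b < B; ++b) {
      std::memcpy(dst + (std::size_t)b * P,
                  X.colptr(b) + (std::size_t)c * P, sizeof(double) * P);
    }
  }
  return out;
}
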
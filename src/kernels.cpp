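// Numeric kernels for the foveal segmentation pipeline:
//   - valid 3D convolution via im2col + GEMM, with full backward pass
//   - affine grid sampling (trilinear / nearest) used for resampling,
//     pyramid extraction and augmentation
//   - 3D connected-component labeling (6/18/26 connectivity)
//   - separable box dilation for the window-estimation neighborhood
//
// Array layout convention (matches R column-major order):
//   feature maps  (D, H, W, C)    per sample, batches append a 5th dim N
//   scalar grids  (D, H, W)
// All indices in this file are 0-based.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gather the im2col matrix (rows = 27*Cin, cols = number of output voxels)
// for one sample of a valid 3x3x3 convolution.
static void im2col3(const double* x, int D, int H, int W, int C,
                    arma::mat& col) {
  const int Do = D - 2, Ho = H - 2, Wo = W - 2;
  long v = 0;
  for (int k = 0; k < Wo; ++k)
    for (int j = 0; j < Ho; ++j)
      for (int i = 0; i < Do; ++i, ++v) {
        double* dst = col.colptr(v); // contiguous writes per output voxel
        for (int c = 0; c < C; ++c) {
          const double* xc = x + (long)c * D * H * W;
          for (int kz = 0; kz < 3; ++kz)
            for (int ky = 0; ky < 3; ++ky) {
              const double* src =
                  xc + i + (long)D * ((j + ky) + (long)H * (k + kz));
              dst[0] = src[0];
              dst[1] = src[1];
              dst[2] = src[2];
              dst += 3;
            }
        }
      }
}

// Scatter-add a dcol matrix back onto the input gradient (col2im).
static void col2im3(const arma::mat& dcol, int D, int H, int W, int C,
                    double* dx) {
  const int Do = D - 2, Ho = H - 2, Wo = W - 2;
  long v = 0;
  for (int k = 0; k < Wo; ++k)
    for (int j = 0; j < Ho; ++j)
      for (int i = 0; i < Do; ++i, ++v) {
        const double* src = dcol.colptr(v); // contiguous reads
        for (int c = 0; c < C; ++c) {
          double* xc = dx + (long)c * D * H * W;
          for (int kz = 0; kz < 3; ++kz)
            for (int ky = 0; ky < 3; ++ky) {
              double* dst =
                  xc + i + (long)D * ((j + ky) + (long)H * (k + kz));
              dst[0] += src[0];
              dst[1] += src[1];
              dst[2] += src[2];
              src += 3;
            }
        }
      }
}

// Valid 3x3x3 convolution, batched.
// x:   (D, H, W, Cin, N); wt: (27*Cin, Cout); b: (Cout)
// returns (D-2, H-2, W-2, Cout, N)
// [[Rcpp::export(name = ".conv3dForward")]]
NumericVector conv3d_forward(NumericVector x, IntegerVector xdim,
                             NumericMatrix wt, NumericVector b) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], N = xdim[4];
  const int Do = D - 2, Ho = H - 2, Wo = W - 2;
  if (Do < 1 || Ho < 1 || Wo < 1) stop("patch too small for valid convolution");
  const int Cout = wt.ncol();
  if (wt.nrow() != 27 * C) stop("weight shape inconsistent with input channels");
  const long nvox = (long)Do * Ho * Wo;
  NumericVector out((long)nvox * Cout * N);
  arma::mat Wm(wt.begin(), wt.nrow(), Cout, false);
  arma::rowvec bv(b.begin(), Cout);
  arma::mat col(27 * C, nvox);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + (long)n * D * H * W * C, D, H, W, C, col);
    arma::mat o = col.t() * Wm; // (nvox x Cout)
    o.each_row() += bv;
    std::copy(o.begin(), o.end(), out.begin() + (long)n * nvox * Cout);
  }
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, Cout, N);
  return out;
}

// Backward pass of the valid convolution above.
// dy: (Do, Ho, Wo, Cout, N); returns list(dx, dwt, db)
// [[Rcpp::export(name = ".conv3dBackward")]]
List conv3d_backward(NumericVector x, IntegerVector xdim, NumericMatrix wt,
                     NumericVector dy) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], N = xdim[4];
  const int Do = D - 2, Ho = H - 2, Wo = W - 2;
  const int Cout = wt.ncol();
  const long nvox = (long)Do * Ho * Wo;
  NumericVector dx((long)D * H * W * C * N);
  arma::mat dW(27 * C, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  arma::mat Wm(wt.begin(), wt.nrow(), Cout, false);
  arma::mat col(27 * C, nvox);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + (long)n * D * H * W * C, D, H, W, C, col);
    arma::mat G(const_cast<double*>(dy.begin()) + (long)n * nvox * Cout,
                nvox, Cout, false);
    dW += col * G;
    db += arma::sum(G, 0);
    arma::mat dcol = Wm * G.t(); // (27C x nvox)
    col2im3(dcol, D, H, W, C, dx.begin() + (long)n * D * H * W * C);
  }
  NumericMatrix dWr(27 * C, Cout);
  std::copy(dW.begin(), dW.end(), dWr.begin());
  dx.attr("dim") = IntegerVector::create(D, H, W, C, N);
  return List::create(_["dx"] = dx, _["dw"] = dWr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Sample a source grid (D,H,W) on an affinely mapped output grid.
// For output voxel v (0-based), the source continuous index is
//   p = M %*% v + t
// mode: 0 = trilinear, 1 = nearest.  Out-of-grid samples get `pad`,
// or the nearest edge value when clampEdges is nonzero.
// [[Rcpp::export(name = ".affineSample")]]
NumericVector affine_sample(NumericVector src, IntegerVector sdim,
                            IntegerVector odim, NumericMatrix M,
                            NumericVector t, int mode, double pad,
                            int clampEdges) {
  const int D = sdim[0], H = sdim[1], W = sdim[2];
  const int Do = odim[0], Ho = odim[1], Wo = odim[2];
  NumericVector out((long)Do * Ho * Wo);
  const double m00 = M(0, 0), m01 = M(0, 1), m02 = M(0, 2);
  const double m10 = M(1, 0), m11 = M(1, 1), m12 = M(1, 2);
  const double m20 = M(2, 0), m21 = M(2, 1), m22 = M(2, 2);
  const double* s = src.begin();
  long v = 0;
  for (int k = 0; k < Wo; ++k)
    for (int j = 0; j < Ho; ++j)
      for (int i = 0; i < Do; ++i, ++v) {
        double px = m00 * i + m01 * j + m02 * k + t[0];
        double py = m10 * i + m11 * j + m12 * k + t[1];
        double pz = m20 * i + m21 * j + m22 * k + t[2];
        if (clampEdges) {
          px = std::min(std::max(px, 0.0), (double)(D - 1));
          py = std::min(std::max(py, 0.0), (double)(H - 1));
          pz = std::min(std::max(pz, 0.0), (double)(W - 1));
        }
        if (mode == 1) { // nearest
          const long ix = (long)std::floor(px + 0.5);
          const long iy = (long)std::floor(py + 0.5);
          const long iz = (long)std::floor(pz + 0.5);
          if (ix < 0 || ix >= D || iy < 0 || iy >= H || iz < 0 || iz >= W)
            out[v] = pad;
          else
            out[v] = s[ix + (long)D * (iy + (long)H * iz)];
        } else { // trilinear with per-corner padding
          const long x0 = (long)std::floor(px), y0 = (long)std::floor(py),
                     z0 = (long)std::floor(pz);
          const double fx = px - x0, fy = py - y0, fz = pz - z0;
          double acc = 0.0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dyy = 0; dyy < 2; ++dyy)
              for (int dxx = 0; dxx < 2; ++dxx) {
                const long cx = x0 + dxx, cy = y0 + dyy, cz = z0 + dz;
                const double wgt = (dxx ? fx : 1 - fx) * (dyy ? fy : 1 - fy) *
                                   (dz ? fz : 1 - fz);
                if (wgt == 0.0) continue;
                double val;
                if (cx < 0 || cx >= D || cy < 0 || cy >= H || cz < 0 ||
                    cz >= W)
                  val = pad;
                else
                  val = s[cx + (long)D * (cy + (long)H * cz)];
                acc += wgt * val;
              }
          out[v] = acc;
        }
      }
  out.attr("dim") = odim;
  return out;
}

// Label connected components of a 3D foreground mask.
// connectivity: 6, 18 or 26.  Ids are assigned in linear scan order.
// [[Rcpp::export(name = ".labelComponents")]]
IntegerVector label_components(IntegerVector mask, IntegerVector mdim,
                               int connectivity) {
  const int D = mdim[0], H = mdim[1], W = mdim[2];
  const long n = (long)D * H * W;
  IntegerVector lab(n);
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        off.push_back({dx, dy, dz});
      }
  int next = 0;
  std::vector<long> stack;
  for (long v0 = 0; v0 < n; ++v0) {
    if (mask[v0] == 0 || lab[v0] != 0) continue;
    ++next;
    lab[v0] = next;
    stack.clear();
    stack.push_back(v0);
    while (!stack.empty()) {
      const long v = stack.back();
      stack.pop_back();
      const int x = (int)(v % D), y = (int)((v / D) % H), z = (int)(v / ((long)D * H));
      for (auto& o : off) {
        const int nx = x + o[0], ny = y + o[1], nz = z + o[2];
        if (nx < 0 || nx >= D || ny < 0 || ny >= H || nz < 0 || nz >= W)
          continue;
        const long u = nx + (long)D * (ny + (long)H * nz);
        if (mask[u] != 0 && lab[u] == 0) {
          lab[u] = next;
          stack.push_back(u);
        }
      }
    }
  }
  lab.attr("dim") = mdim;
  return lab;
}

// Binary box dilation with a (2r+1)^3 structuring element, run as three
// separable 1D max passes (equivalent to 26-connected dilation iterated r
// times for a box element).
// [[Rcpp::export(name = ".boxDilate")]]
LogicalVector box_dilate(LogicalVector mask, IntegerVector mdim, int radius) {
  const int D = mdim[0], H = mdim[1], W = mdim[2];
  const long n = (long)D * H * W;
  std::vector<char> a(n), b(n);
  for (long i = 0; i < n; ++i) a[i] = mask[i] ? 1 : 0;
  const int dims[3] = {D, H, W};
  const long strides[3] = {1, D, (long)D * H};
  for (int ax = 0; ax < 3; ++ax) {
    const int len = dims[ax];
    const long st = strides[ax];
    for (long base = 0; base < n; ++base) {
      // only iterate voxels whose coordinate along ax is 0
      long coord = (base / st) % len;
      if (coord != 0) continue;
      for (int i = 0; i < len; ++i) {
        char m = 0;
        const int lo = std::max(0, i - radius), hi = std::min(len - 1, i + radius);
        for (int j = lo; j <= hi && !m; ++j) m = a[base + (long)j * st];
        b[base + (long)i * st] = m;
      }
    }
    std::swap(a, b);
  }
  LogicalVector out(n);
  for (long i = 0; i < n; ++i) out[i] = a[i] != 0;
  out.attr("dim") = mdim;
  return out;
}

// Fused batch-norm + ReLU forward.  x: (D,H,W,C,N).  In training mode
// batch statistics are used and the running buffers updated with the
// given momentum; in eval mode the running statistics are used.
// [[Rcpp::export(name = ".bnReluForward")]]
List bn_relu_forward(NumericVector x, IntegerVector xdim,
                     NumericVector gamma, NumericVector beta,
                     NumericVector runMean, NumericVector runVar,
                     double momentum, double eps, int train) {
  const long DHW = (long)xdim[0] * xdim[1] * xdim[2];
  const int C = xdim[3], N = xdim[4];
  const long n = DHW * C * N;
  NumericVector y(n), xhat(n);
  NumericVector invstd(C), rm(C), rv(C);
  std::vector<double> mu(C), var(C);
  if (train) {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int b = 0; b < N; ++b) {
        const double* p = x.begin() + ((long)b * C + c) * DHW;
        for (long i = 0; i < DHW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      }
      const double m = (double)DHW * N;
      mu[c] = s / m;
      var[c] = std::max(s2 / m - mu[c] * mu[c], 0.0);
      rm[c] = (1 - momentum) * runMean[c] + momentum * mu[c];
      rv[c] = (1 - momentum) * runVar[c] + momentum * var[c];
    }
  } else {
    for (int c = 0; c < C; ++c) {
      mu[c] = runMean[c];
      var[c] = runVar[c];
      rm[c] = runMean[c];
      rv[c] = runVar[c];
    }
  }
  for (int c = 0; c < C; ++c) {
    const double is = 1.0 / std::sqrt(var[c] + eps);
    invstd[c] = is;
    const double g = gamma[c], bshift = beta[c], m0 = mu[c];
    for (int b = 0; b < N; ++b) {
      const long off = ((long)b * C + c) * DHW;
      const double* p = x.begin() + off;
      double* ph = xhat.begin() + off;
      double* py = y.begin() + off;
      for (long i = 0; i < DHW; ++i) {
        const double xh = (p[i] - m0) * is;
        ph[i] = xh;
        const double v = g * xh + bshift;
        py[i] = v > 0 ? v : 0;
      }
    }
  }
  y.attr("dim") = xdim;
  xhat.attr("dim") = xdim;
  return List::create(_["y"] = y, _["xhat"] = xhat,
                      _["invstd"] = invstd, _["runMean"] = rm,
                      _["runVar"] = rv);
}

// Fused ReLU + batch-norm backward.  da is the gradient w.r.t. the
// post-ReLU output; y the post-ReLU output (mask = y > 0).
// [[Rcpp::export(name = ".bnReluBackward")]]
List bn_relu_backward(NumericVector da, NumericVector y, NumericVector xhat,
                      IntegerVector xdim, NumericVector invstd,
                      NumericVector gamma) {
  const long DHW = (long)xdim[0] * xdim[1] * xdim[2];
  const int C = xdim[3], N = xdim[4];
  NumericVector dx((long)DHW * C * N), dgamma(C), dbeta(C);
  const double m = (double)DHW * N;
  for (int c = 0; c < C; ++c) {
    double s1 = 0, s2 = 0;
    for (int b = 0; b < N; ++b) {
      const long off = ((long)b * C + c) * DHW;
      const double* pa = da.begin() + off;
      const double* py = y.begin() + off;
      const double* ph = xhat.begin() + off;
      for (long i = 0; i < DHW; ++i) {
        const double g = py[i] > 0 ? pa[i] : 0.0;
        s1 += g;
        s2 += g * ph[i];
      }
    }
    dbeta[c] = s1;
    dgamma[c] = s2;
    const double coef = gamma[c] * invstd[c];
    const double c1 = s1 / m, c2 = s2 / m;
    for (int b = 0; b < N; ++b) {
      const long off = ((long)b * C + c) * DHW;
      const double* pa = da.begin() + off;
      const double* py = y.begin() + off;
      const double* ph = xhat.begin() + off;
      double* px = dx.begin() + off;
      for (long i = 0; i < DHW; ++i) {
        const double g = py[i] > 0 ? pa[i] : 0.0;
        px[i] = coef * (g - c1 - ph[i] * c2);
      }
    }
  }
  dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Mean cross-entropy and its gradient w.r.t. the logits, fused.
// probs: (m1,m2,m3,C,N); labels: int (m1,m2,m3,N) with values 0..C-1.
// weights: per-class weights or empty for uniform.
// [[Rcpp::export(name = ".ceLossGrad")]]
List ce_loss_grad(NumericVector probs, IntegerVector pdim,
                  IntegerVector labels, NumericVector weights) {
  const long V = (long)pdim[0] * pdim[1] * pdim[2];
  const int C = pdim[3], N = pdim[4];
  NumericVector dlogits((long)V * C * N);
  const bool wtd = weights.size() > 0;
  double wsum = 0, loss = 0;
  if (!wtd) wsum = (double)V * N;
  else {
    for (int b = 0; b < N; ++b)
      for (long i = 0; i < V; ++i)
        wsum += weights[labels[(long)b * V + i]];
  }
  for (int b = 0; b < N; ++b) {
    const long poff = (long)b * V * C;
    for (long i = 0; i < V; ++i) {
      const int lab = labels[(long)b * V + i];
      const double w = wtd ? weights[lab] : 1.0;
      const double p = std::max(probs[poff + (long)lab * V + i], 1e-7);
      loss += -std::log(p) * w;
      for (int c = 0; c < C; ++c) {
        const double pc = probs[poff + (long)c * V + i];
        dlogits[poff + (long)c * V + i] =
            ((c == lab) ? (pc - 1.0) : pc) * w / wsum;
      }
    }
  }
  dlogits.attr("dim") = pdim;
  return List::create(_["loss"] = loss / wsum, _["dlogits"] = dlogits);
}

// Nearest-neighbor 2x upsampling of (D,H,W,C,N) and its adjoint.
// [[Rcpp::export(name = ".upsample2Nearest")]]
NumericVector upsample2_nearest(NumericVector x, IntegerVector xdim) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], N = xdim[4];
  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  NumericVector y((long)Do * Ho * Wo * C * N);
  long v = 0;
  for (int q = 0; q < C * N; ++q) {
    const double* src = x.begin() + (long)q * D * H * W;
    for (int k = 0; k < Wo; ++k)
      for (int j = 0; j < Ho; ++j) {
        const double* row = src + (long)D * ((j >> 1) + (long)H * (k >> 1));
        for (int i = 0; i < Do; ++i, ++v) y[v] = row[i >> 1];
      }
  }
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export(name = ".upsample2NearestBackward")]]
NumericVector upsample2_nearest_backward(NumericVector dy,
                                         IntegerVector ydim) {
  const int Do = ydim[0], Ho = ydim[1], Wo = ydim[2], C = ydim[3],
            N = ydim[4];
  const int D = Do / 2, H = Ho / 2, W = Wo / 2;
  NumericVector dx((long)D * H * W * C * N);
  long v = 0;
  for (int q = 0; q < C * N; ++q) {
    double* dst = dx.begin() + (long)q * D * H * W;
    for (int k = 0; k < Wo; ++k)
      for (int j = 0; j < Ho; ++j) {
        double* row = dst + (long)D * ((j >> 1) + (long)H * (k >> 1));
        for (int i = 0; i < Do; ++i, ++v) row[i >> 1] += dy[v];
      }
  }
  dx.attr("dim") = IntegerVector::create(D, H, W, C, N);
  return dx;
}
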
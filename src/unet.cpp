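// Encoder-decoder ("U-Net" style) convolutional network engine.
#include <functional>
#include <map>
//
// The analysis networks are small enough (tens of thousands of parameters at
// test scale) that a hand-rolled im2col + BLAS implementation trains them on
// one CPU core in minutes.  Layout, forward pass and backward pass live here;
// weight initialisation, the Adam loop and all user-facing contracts live in
// R (R/networks.R).
//
// Conventions:
//  - tensors are arma::cube (rows = image rows, cols = image cols, slices =
//    channels), matching R's array(dim = c(H, W, C)) memory layout;
//  - 3x3 convolutions are "same" (zero padding), followed by ReLU;
//  - down-sampling is 2x2 max-pooling, up-sampling is a learned 2x2
//    stride-2 transposed convolution followed by ReLU;
//  - skip connections concatenate [up-sampled, skip] along channels;
//  - the final layer is a 1x1 convolution with sigmoid (1 output channel)
//    or per-pixel softmax (>= 2 output channels).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

namespace {

const double LOSS_EPS = 1e-7;

struct LayerSpec {
  int type;      // 0 = conv3x3, 1 = upconv2x2, 2 = conv1x1
  int cin, cout;
  size_t wOff, bOff, wLen;
};

std::vector<LayerSpec> build_layout(int levels, int base, int in_ch,
                                    int out_ch, size_t& total) {
  std::vector<LayerSpec> specs;
  size_t pos = 0;
  auto add = [&](int type, int cin, int cout) {
    int k = (type == 0) ? 9 : (type == 1 ? 4 : 1);
    LayerSpec s;
    s.type = type; s.cin = cin; s.cout = cout;
    s.wLen = (size_t)k * cin * cout;
    s.wOff = pos; pos += s.wLen;
    s.bOff = pos; pos += cout;
    specs.push_back(s);
  };
  // contracting path
  for (int d = 0; d < levels; ++d) {
    int F = base << d;
    int cin = (d == 0) ? in_ch : (base << (d - 1));
    add(0, cin, F);
    add(0, F, F);
  }
  // expanding path
  for (int d = levels - 2; d >= 0; --d) {
    int F = base << d;
    add(1, base << (d + 1), F);
    add(0, 2 * F, F);
    add(0, F, F);
  }
  add(2, base, out_ch);
  total = pos;
  return specs;
}

mat im2col3(const cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  mat P((size_t)H * W, 9 * (size_t)C, fill::zeros);
  int col = 0;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = 0; c < C; ++c) {
        mat Z(H, W, fill::zeros);
        int r0 = std::max(0, -a), r1 = std::min(H, H - a);
        int c0 = std::max(0, -b), c1 = std::min(W, W - b);
        if (r1 > r0 && c1 > c0)
          Z.submat(r0, c0, r1 - 1, c1 - 1) =
            X.slice(c).submat(r0 + a, c0 + b, r1 - 1 + a, c1 - 1 + b);
        P.col(col++) = vectorise(Z);
      }
  return P;
}

void col2im3(const mat& dP, cube& dX) {
  const int H = dX.n_rows, W = dX.n_cols, C = dX.n_slices;
  int col = 0;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = 0; c < C; ++c) {
        mat Z = reshape(dP.col(col++), H, W);
        int r0 = std::max(0, -a), r1 = std::min(H, H - a);
        int c0 = std::max(0, -b), c1 = std::min(W, W - b);
        if (r1 > r0 && c1 > c0)
          dX.slice(c).submat(r0 + a, c0 + b, r1 - 1 + a, c1 - 1 + b) +=
            Z.submat(r0, c0, r1 - 1, c1 - 1);
      }
}

inline mat cube_flat(const cube& X) {
  return mat(const_cast<double*>(X.memptr()),
             (size_t)X.n_rows * X.n_cols, X.n_slices, true);
}

inline cube mat_cube(const mat& M, int H, int W) {
  return cube(const_cast<double*>(M.memptr()), H, W, M.n_cols, true);
}

struct Cache {
  mat P;     // layer input, im2col (conv3/conv1) or flat (upconv)
  mat A;     // post-activation, flat (for the ReLU mask)
  int Hin, Win;
};

// One full forward pass; caches are filled only when `store` is true.
cube forward_pass(const double* pp, const std::vector<LayerSpec>& specs,
                  const cube& input, int levels, bool softmax_out,
                  std::vector<Cache>* caches, std::vector<cube>* skips,
                  std::vector<uvec>* poolidx) {
  cube cur = input;
  size_t li = 0;

  auto conv3relu = [&](const cube& X, const LayerSpec& s) {
    mat P = im2col3(X);
    mat Wm(const_cast<double*>(pp) + s.wOff, 9 * (size_t)s.cin, s.cout, false, true);
    rowvec b(const_cast<double*>(pp) + s.bOff, s.cout, false, true);
    mat Y = P * Wm;
    Y.each_row() += b;
    Y.transform([](double v) { return v > 0.0 ? v : 0.0; });
    if (caches) {
      (*caches)[li].P = std::move(P);
      (*caches)[li].A = Y;
      (*caches)[li].Hin = X.n_rows; (*caches)[li].Win = X.n_cols;
    }
    return mat_cube(Y, X.n_rows, X.n_cols);
  };

  auto upconvrelu = [&](const cube& X, const LayerSpec& s) {
    const int H = X.n_rows, W = X.n_cols;
    mat Xf = cube_flat(X);
    rowvec b(const_cast<double*>(pp) + s.bOff, s.cout, false, true);
    cube Y(2 * H, 2 * W, s.cout, fill::zeros);
    for (int a = 0; a < 2; ++a)
      for (int bb = 0; bb < 2; ++bb) {
        mat Wab(const_cast<double*>(pp) + s.wOff +
                  (size_t)(a * 2 + bb) * s.cin * s.cout,
                s.cin, s.cout, false, true);
        mat Yab = Xf * Wab;
        uvec rows = regspace<uvec>(a, 2, 2 * H - 1);
        uvec cols = regspace<uvec>(bb, 2, 2 * W - 1);
        for (int o = 0; o < s.cout; ++o)
          Y.slice(o)(rows, cols) = reshape(Yab.col(o), H, W);
      }
    for (int o = 0; o < s.cout; ++o) Y.slice(o) += b(o);
    Y.transform([](double v) { return v > 0.0 ? v : 0.0; });
    if (caches) {
      (*caches)[li].P = std::move(Xf);
      (*caches)[li].A = cube_flat(Y);
      (*caches)[li].Hin = H; (*caches)[li].Win = W;
    }
    return Y;
  };

  // contracting path
  for (int d = 0; d < levels; ++d) {
    cur = conv3relu(cur, specs[li]); ++li;
    cur = conv3relu(cur, specs[li]); ++li;
    if (d < levels - 1) {
      if (skips) (*skips)[d] = cur;
      const int H = cur.n_rows, W = cur.n_cols, C = cur.n_slices;
      cube pooled(H / 2, W / 2, C);
      uvec idx;
      if (poolidx) idx.set_size((size_t)(H / 2) * (W / 2) * C);
      for (int c = 0; c < C; ++c)
        for (int j = 0; j < W / 2; ++j)
          for (int i = 0; i < H / 2; ++i) {
            double best = -datum::inf; int bi = 0, bj = 0;
            for (int a = 0; a < 2; ++a)
              for (int bb = 0; bb < 2; ++bb) {
                double v = cur(2 * i + a, 2 * j + bb, c);
                if (v > best) { best = v; bi = a; bj = bb; }
              }
            pooled(i, j, c) = best;
            if (poolidx)
              idx((size_t)c * (H / 2) * (W / 2) + (size_t)j * (H / 2) + i) =
                (size_t)c * H * W + (size_t)(2 * j + bj) * H + (2 * i + bi);
          }
      if (poolidx) (*poolidx)[d] = std::move(idx);
      cur = pooled;
    }
  }
  // expanding path
  for (int d = levels - 2; d >= 0; --d) {
    cur = upconvrelu(cur, specs[li]); ++li;
    cur = join_slices(cur, skips ? (*skips)[d] : cube());
    // when not caching, skips is still needed: caller always provides skips
    cur = conv3relu(cur, specs[li]); ++li;
    cur = conv3relu(cur, specs[li]); ++li;
  }
  // final 1x1 conv
  const LayerSpec& fs = specs[li];
  mat P = cube_flat(cur);
  mat Wm(const_cast<double*>(pp) + fs.wOff, fs.cin, fs.cout, false, true);
  rowvec b(const_cast<double*>(pp) + fs.bOff, fs.cout, false, true);
  mat Z = P * Wm;
  Z.each_row() += b;
  if (caches) {
    (*caches)[li].P = std::move(P);
    (*caches)[li].Hin = cur.n_rows; (*caches)[li].Win = cur.n_cols;
  }
  const int H = cur.n_rows, W = cur.n_cols;
  if (softmax_out) {
    Z.each_col() -= max(Z, 1);
    Z = exp(Z);
    Z.each_col() /= sum(Z, 1);
  } else {
    Z = 1.0 / (1.0 + exp(-Z));
  }
  return mat_cube(Z, H, W);
}

std::vector<LayerSpec> layout_of(int levels, int base, int in_ch, int out_ch) {
  size_t total;
  return build_layout(levels, base, in_ch, out_ch, total);
}

}  // namespace

// [[Rcpp::export]]
List unet_layout_cpp(int levels, int base_filters, int in_channels,
                     int out_channels) {
  size_t total;
  std::vector<LayerSpec> specs =
    build_layout(levels, base_filters, in_channels, out_channels, total);
  List out(specs.size());
  for (size_t i = 0; i < specs.size(); ++i) {
    const LayerSpec& s = specs[i];
    int k = (s.type == 0) ? 9 : (s.type == 1 ? 4 : 1);
    out[i] = List::create(_["type"] = s.type, _["fan_in"] = k * s.cin,
                          _["cout"] = s.cout, _["wlen"] = (double)s.wLen,
                          _["blen"] = s.cout);
  }
  out.attr("n_params") = (double)total;
  return out;
}

// [[Rcpp::export]]
NumericVector unet_forward_cpp(NumericVector params, NumericVector x,
                               int levels, int base_filters, int in_channels,
                               int out_channels, bool softmax_out) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1];
  cube X(x.begin(), H, W, in_channels);
  std::vector<LayerSpec> specs =
    layout_of(levels, base_filters, in_channels, out_channels);
  std::vector<cube> skips(std::max(levels - 1, 0));
  // skips are needed structurally even without caching
  std::vector<Cache> caches;  // unused
  cube Y = forward_pass(params.begin(), specs, X, levels, softmax_out,
                        nullptr, &skips, nullptr);
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(H, W, out_channels);
  return out;
}

// [[Rcpp::export]]
List unet_lossgrad_cpp(NumericVector params, NumericVector x,
                       NumericVector target, NumericVector wmap, int levels,
                       int base_filters, int in_channels, int out_channels,
                       bool softmax_out) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1];
  const size_t npix = (size_t)H * W;
  cube X(x.begin(), H, W, in_channels);
  cube T(target.begin(), H, W, out_channels);

  size_t total;
  std::vector<LayerSpec> specs =
    build_layout(levels, base_filters, in_channels, out_channels, total);
  std::vector<Cache> caches(specs.size());
  std::vector<cube> skips(std::max(levels - 1, 0));
  std::vector<uvec> poolidx(std::max(levels - 1, 0));
  cube P = forward_pass(params.begin(), specs, X, levels, softmax_out,
                        &caches, &skips, &poolidx);

  // loss + gradient at the logits
  mat Pf = cube_flat(P);
  mat Tf = cube_flat(T);
  double loss;
  mat dZ;
  if (softmax_out) {
    mat Pc = clamp(Pf, LOSS_EPS, 1.0);
    loss = -accu(Tf % log(Pc)) / (double)npix;
    dZ = (Pf - Tf) / (double)npix;
  } else {
    vec w(wmap.begin(), npix);
    mat Pc = clamp(Pf, LOSS_EPS, 1.0 - LOSS_EPS);
    loss = accu((w % (-Tf.col(0) % log(Pc.col(0)) -
                      (1.0 - Tf.col(0)) % log(1.0 - Pc.col(0))))) /
           (double)npix;
    dZ = ((Pf.col(0) - Tf.col(0)) % w) / (double)npix;
  }

  NumericVector grad(params.size());
  double* gp = grad.begin();
  const double* pp = params.begin();

  size_t li = specs.size() - 1;

  auto back_conv = [&](const mat& dY_relu_masked_or_logit, bool relu) -> cube {
    const LayerSpec& s = specs[li];
    const Cache& c = caches[li];
    mat gm = dY_relu_masked_or_logit;
    if (relu) gm %= conv_to<mat>::from(c.A > 0);
    mat Gw(gp + s.wOff, c.P.n_cols, s.cout, false, true);
    Gw += c.P.t() * gm;
    rowvec Gb(gp + s.bOff, s.cout, false, true);
    Gb += sum(gm, 0);
    mat Wm(const_cast<double*>(pp) + s.wOff, c.P.n_cols, s.cout, false, true);
    mat dP = gm * Wm.t();
    if (s.type == 2) {  // 1x1: dP is already dX flat
      return mat_cube(dP, c.Hin, c.Win);
    }
    cube dX(c.Hin, c.Win, s.cin, fill::zeros);
    col2im3(dP, dX);
    return dX;
  };

  auto back_upconv = [&](const cube& dY) -> cube {
    const LayerSpec& s = specs[li];
    const Cache& c = caches[li];
    mat gm = cube_flat(dY);
    gm %= conv_to<mat>::from(c.A > 0);
    cube G = mat_cube(gm, dY.n_rows, dY.n_cols);
    rowvec Gb(gp + s.bOff, s.cout, false, true);
    Gb += sum(gm, 0);
    const int H0 = c.Hin, W0 = c.Win;
    mat dXf((size_t)H0 * W0, s.cin, fill::zeros);
    for (int a = 0; a < 2; ++a)
      for (int bb = 0; bb < 2; ++bb) {
        uvec rows = regspace<uvec>(a, 2, 2 * H0 - 1);
        uvec cols = regspace<uvec>(bb, 2, 2 * W0 - 1);
        mat Gab((size_t)H0 * W0, s.cout);
        for (int o = 0; o < s.cout; ++o) {
          mat sub = G.slice(o)(rows, cols);
          Gab.col(o) = vectorise(sub);
        }
        size_t off = s.wOff + (size_t)(a * 2 + bb) * s.cin * s.cout;
        mat Gw(gp + off, s.cin, s.cout, false, true);
        Gw += c.P.t() * Gab;
        mat Wab(const_cast<double*>(pp) + off, s.cin, s.cout, false, true);
        dXf += Gab * Wab.t();
      }
    return mat_cube(dXf, H0, W0);
  };

  // final 1x1 conv
  cube g = back_conv(dZ, false);
  --li;

  // expanding path in reverse (forward ran d = levels-2 .. 0)
  std::vector<cube> dskip(std::max(levels - 1, 0));
  for (int d = 0; d <= levels - 2; ++d) {
    cube gc = back_conv(cube_flat(g), true); --li;   // second conv of block
    gc = back_conv(cube_flat(gc), true); --li;       // first conv (input = concat)
    const int F = base_filters << d;
    cube d_up = gc.slices(0, F - 1);
    dskip[d] = gc.slices(F, 2 * F - 1);
    g = back_upconv(d_up); --li;
  }

  // contracting path in reverse (forward ran d = 0 .. levels-1)
  for (int d = levels - 1; d >= 0; --d) {
    if (d < levels - 1) {
      // g is the gradient at the pooled tensor of level d's output
      const cube& sk = skips[d];
      cube gfull(sk.n_rows, sk.n_cols, sk.n_slices, fill::zeros);
      const uvec& idx = poolidx[d];
      const double* src = g.memptr();
      double* dst = gfull.memptr();
      for (size_t k = 0; k < idx.n_elem; ++k) dst[idx(k)] += src[k];
      g = gfull + dskip[d];
    }
    g = back_conv(cube_flat(g), true); --li;
    cube gin = back_conv(cube_flat(g), true);
    if (li > 0) --li;
    g = gin;
  }

  return List::create(_["loss"] = loss, _["grad"] = grad);
}

// 8-connected component labelling of a binary matrix (union-find).
// [[Rcpp::export]]
IntegerMatrix label8_cpp(NumericMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<int> parent((size_t)H * W, -1);
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
    return i;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0) continue;
      int id = i + j * H;
      parent[id] = id;
      // neighbours already initialised (previous cols / rows)
      const int di[4] = {-1, -1, -1, 0};
      const int dj[4] = {-1, 0, 1, -1};
      for (int k = 0; k < 4; ++k) {
        int ni = i + di[k], nj = j + dj[k];
        if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
        // note: (i-1, j+1) is a forward column; handle via backward set only
        if (nj > j) continue;
        if (nj == j && ni > i) continue;
        if (mask(ni, nj) != 0) unite(id, ni + nj * H);
      }
      // the (i+1, j-1) diagonal neighbour (previous column, next row)
      int ni = i + 1, nj = j - 1;
      if (ni < H && nj >= 0 && mask(ni, nj) != 0) unite(id, ni + nj * H);
    }
  IntegerMatrix lab(H, W);
  std::map<int, int> remap;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0) { lab(i, j) = 0; continue; }
      int r = find(i + j * H);
      auto it = remap.find(r);
      if (it == remap.end()) {
        int nid = (int)remap.size() + 1;
        remap[r] = nid;
        lab(i, j) = nid;
      } else {
        lab(i, j) = it->second;
      }
    }
  return lab;
}
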
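// 3D encoder-decoder segmentation network (context/localization design with
// instance normalization, leaky ReLU, residual context blocks and deep
// supervision by summed side outputs), with hand-written backpropagation.
// Feature maps are stored as (nvox x channels) matrices, voxels ordered
// x-fastest (column-major), so 3x3x3 convolutions become im2col + GEMM.
// Internals run in single precision (double at the R boundary).
#include <RcppArmadillo.h>
#include <random>
#include <cstring>
#ifdef __GLIBC__
#include <malloc.h>
// keep large buffers on the heap instead of mmap round-trips; the conv
// workspaces are reallocated every step and mmap churn dominates otherwise
static const bool malloc_tuned = []() {
  mallopt(M_MMAP_THRESHOLD, 256 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 256 * 1024 * 1024);
  return true;
}();
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

typedef float real;
typedef arma::fmat rmat;
typedef arma::frowvec rrowvec;
typedef arma::fvec rcol;
using arma::uvec;

struct UCfg {
  int inC, outC, F, depth;
  real slope, dropout;
  bool softmax;
};

static UCfg parse_cfg(List cfg) {
  UCfg c;
  c.inC = as<int>(cfg["in_channels"]);
  c.outC = as<int>(cfg["out_channels"]);
  c.F = as<int>(cfg["base_filters"]);
  c.depth = 4;
  c.slope = cfg.containsElementNamed("negative_slope")
                ? (real)as<double>(cfg["negative_slope"]) : (real)0.01;
  c.dropout = cfg.containsElementNamed("dropout")
                  ? (real)as<double>(cfg["dropout"]) : (real)0.3;
  std::string act = as<std::string>(cfg["final_activation"]);
  c.softmax = (act == "softmax");
  return c;
}

// One convolutional unit: k^3 conv (+bias), optional instance norm, optional
// leaky ReLU. Blocks are created in a fixed order which also defines the
// layout of the flat parameter vector.
struct Block {
  std::string name;
  int k;              // kernel edge: 3 or 1
  int Cin, Cout, stride;
  bool norm, act;
  // forward caches (training mode)
  rmat in;            // input features
  int Xi, Yi, Zi, Xo, Yo, Zo;
  rmat xhat;          // instance-norm cache
  rrowvec invstd;
  rmat y;             // post-activation output (sign cache for lrelu)
  rmat colcache;      // im2col buffer kept for the backward pass
};

static std::vector<Block> build_blocks(const UCfg& c) {
  std::vector<Block> B;
  auto add = [&](std::string n, int k, int ci, int co, int s, bool nm, bool ac) {
    Block b;
    b.name = n; b.k = k; b.Cin = ci; b.Cout = co; b.stride = s;
    b.norm = nm; b.act = ac;
    B.push_back(std::move(b));
  };
  std::vector<int> C(c.depth + 1);
  for (int l = 0; l <= c.depth; ++l) C[l] = c.F << l;
  add("enc0.conv", 3, c.inC, C[0], 1, true, true);
  add("ctx0.c1", 3, C[0], C[0], 1, true, true);
  add("ctx0.c2", 3, C[0], C[0], 1, true, true);
  for (int l = 1; l <= c.depth; ++l) {
    std::string p = "L" + std::to_string(l);
    add(p + ".down", 3, C[l - 1], C[l], 2, true, true);
    add(p + ".ctx.c1", 3, C[l], C[l], 1, true, true);
    add(p + ".ctx.c2", 3, C[l], C[l], 1, true, true);
  }
  for (int l = c.depth - 1; l >= 0; --l) {
    std::string p = "U" + std::to_string(l);
    add(p + ".up", 3, C[l + 1], C[l], 1, true, true);
    add(p + ".loc.a", 3, 2 * C[l], 2 * C[l], 1, true, true);
    add(p + ".loc.b", 1, 2 * C[l], C[l], 1, true, true);
  }
  for (int l = 2; l >= 0; --l)
    add("seg" + std::to_string(l), 1, C[l], c.outC, 1, false, false);
  return B;
}

// [[Rcpp::export]]
List cpp_unet_param_info(List cfg) {
  UCfg c = parse_cfg(cfg);
  std::vector<Block> B = build_blocks(c);
  std::vector<std::string> names;
  std::vector<int> lens;
  std::vector<std::string> types;
  std::vector<double> fans;
  for (auto& b : B) {
    int ke = b.k * b.k * b.k;
    names.push_back(b.name + ".W");
    lens.push_back(ke * b.Cin * b.Cout);
    types.push_back("conv");
    fans.push_back(ke * b.Cin);
    names.push_back(b.name + ".b");
    lens.push_back(b.Cout);
    types.push_back("bias");
    fans.push_back(0);
    if (b.norm) {
      names.push_back(b.name + ".norm");
      lens.push_back(2 * b.Cout);
      types.push_back("norm");
      fans.push_back(0);
    }
  }
  return List::create(_["name"] = names, _["length"] = lens,
                      _["type"] = types, _["fan_in"] = fans);
}

// ---- conv primitives -------------------------------------------------------

// valid output-x range [lo, hi) for input size X, offset dx, stride s
static inline void xo_range(int X, int Xo, int dx, int s, int& lo, int& hi) {
  lo = 0;
  while (lo < Xo && lo * s + dx < 0) ++lo;
  hi = Xo;
  while (hi > lo && (hi - 1) * s + dx >= X) --hi;
}

// im2col for a z-range of output voxels; col is (Xo*Yo*(z1-z0)) x (k^3*Cin),
// column index = c*k^3 + kidx, zero-padded (pad = (k-1)/2).
static void im2col_chunk(const rmat& in, int X, int Y, int Z, int k, int stride,
                         int Xo, int Yo, int z0, int z1, rmat& col) {
  const int ke = k * k * k, pad = (k - 1) / 2;
  const int Cin = in.n_cols;
  col.set_size((size_t)Xo * Yo * (z1 - z0), (size_t)ke * Cin);
  for (int c = 0; c < Cin; ++c) {
    const real* src = in.colptr(c);
    for (int kk = 0; kk < ke; ++kk) {
      int dx = kk % k - pad, dy = (kk / k) % k - pad, dz = kk / (k * k) - pad;
      int lo, hi;
      xo_range(X, Xo, dx, stride, lo, hi);
      real* dst = col.colptr((size_t)c * ke + kk);
      size_t r = 0;
      for (int zo = z0; zo < z1; ++zo) {
        int z = zo * stride + dz;
        bool zok = (z >= 0 && z < Z);
        for (int yo = 0; yo < Yo; ++yo) {
          int y = yo * stride + dy;
          if (!zok || y < 0 || y >= Y) {
            std::memset(dst + r, 0, sizeof(real) * Xo);
            r += Xo;
            continue;
          }
          const real* s2 = src + (size_t)X * ((size_t)y + (size_t)Y * z);
          if (lo > 0) std::memset(dst + r, 0, sizeof(real) * lo);
          if (stride == 1) {
            std::memcpy(dst + r + lo, s2 + lo + dx, sizeof(real) * (hi - lo));
          } else {
            for (int xo = lo; xo < hi; ++xo)
              dst[r + xo] = s2[xo * stride + dx];
          }
          if (hi < Xo) std::memset(dst + r + hi, 0, sizeof(real) * (Xo - hi));
          r += Xo;
        }
      }
    }
  }
}

static void col2im_chunk(const rmat& dcol, int X, int Y, int Z, int k,
                         int stride, int Xo, int Yo, int z0, int z1, rmat& din) {
  const int ke = k * k * k, pad = (k - 1) / 2;
  const int Cin = din.n_cols;
  for (int c = 0; c < Cin; ++c) {
    real* dst = din.colptr(c);
    for (int kk = 0; kk < ke; ++kk) {
      int dx = kk % k - pad, dy = (kk / k) % k - pad, dz = kk / (k * k) - pad;
      int lo, hi;
      xo_range(X, Xo, dx, stride, lo, hi);
      const real* src = dcol.colptr((size_t)c * ke + kk);
      size_t r = 0;
      for (int zo = z0; zo < z1; ++zo) {
        int z = zo * stride + dz;
        bool zok = (z >= 0 && z < Z);
        for (int yo = 0; yo < Yo; ++yo) {
          int y = yo * stride + dy;
          if (!zok || y < 0 || y >= Y) { r += Xo; continue; }
          real* s2 = dst + (size_t)X * ((size_t)y + (size_t)Y * z);
          if (stride == 1) {
            real* d2 = s2 + dx;
            for (int xo = lo; xo < hi; ++xo) d2[xo] += src[r + xo];
          } else {
            for (int xo = lo; xo < hi; ++xo) s2[xo * stride + dx] += src[r + xo];
          }
          r += Xo;
        }
      }
    }
  }
}

static int chunk_slices(int Xo, int Yo, int Zo, int cols) {
  // keep each im2col buffer under ~64M floats (256 MB)
  double per_slice = (double)Xo * Yo * cols;
  int zc = (int)std::floor(6.4e7 / std::max(per_slice, 1.0));
  return std::max(1, std::min(Zo, zc));
}

struct Params {
  std::vector<rmat> W, Nrm;
  std::vector<rrowvec> Bv;
};

// Split a flat double vector into per-block single-precision matrices.
static Params unpack_params(const UCfg& c, const std::vector<Block>& B,
                            const NumericVector& theta) {
  Params P;
  size_t off = 0;
  const double* p = theta.begin();
  auto take = [&](size_t n) {
    const double* q = p + off;
    off += n;
    return q;
  };
  for (auto& b : B) {
    int ke = b.k * b.k * b.k;
    size_t nw = (size_t)ke * b.Cin * b.Cout;
    const double* q = take(nw);
    rmat W(ke * b.Cin, b.Cout);
    for (size_t i = 0; i < nw; ++i) W(i) = (real)q[i];
    P.W.push_back(std::move(W));
    q = take(b.Cout);
    rrowvec bv(b.Cout);
    for (int i = 0; i < b.Cout; ++i) bv(i) = (real)q[i];
    P.Bv.push_back(std::move(bv));
    if (b.norm) {
      q = take(2 * (size_t)b.Cout);
      rmat nm(b.Cout, 2);
      for (size_t i = 0; i < 2 * (size_t)b.Cout; ++i) nm(i) = (real)q[i];
      P.Nrm.push_back(std::move(nm));
    } else {
      P.Nrm.push_back(rmat());
    }
  }
  if (off != (size_t)theta.size())
    stop("parameter vector has wrong length (%d expected, %d given)",
         (int)off, (int)theta.size());
  return P;
}

struct Grads {
  std::vector<rmat> W, Nrm;
  std::vector<rrowvec> Bv;
};

static Grads zero_grads(const std::vector<Block>& B) {
  Grads G;
  for (auto& b : B) {
    int ke = b.k * b.k * b.k;
    G.W.emplace_back(arma::zeros<rmat>(ke * b.Cin, b.Cout));
    G.Bv.emplace_back(arma::zeros<rrowvec>(b.Cout));
    G.Nrm.emplace_back(b.norm ? arma::zeros<rmat>(b.Cout, 2) : rmat());
  }
  return G;
}

static const real IN_EPS = (real)1e-5;

struct UNet {
  UCfg c;
  std::vector<Block> B;
  const Params* P;
  Grads* G;
  bool train;
  std::mt19937_64 rng;
  std::vector<rmat> dropmask;  // one per context block
  // graph caches
  std::vector<rmat> skip;      // s_0..s_depth
  std::vector<int> dims;       // (X,Y,Z) at each level
  std::vector<rmat> skip_grad;

  UNet(const UCfg& cc, const Params& PP, Grads* GG, bool tr, uint64_t seed)
      : c(cc), B(build_blocks(cc)), P(&PP), G(GG), train(tr), rng(seed) {
    dropmask.resize(c.depth + 1);
  }

  rmat block_fwd(int i, const rmat& in, int X, int Y, int Z) {
    Block& b = B[i];
    b.Xi = X; b.Yi = Y; b.Zi = Z;
    b.Xo = (b.stride == 1) ? X : X / 2;
    b.Yo = (b.stride == 1) ? Y : Y / 2;
    b.Zo = (b.stride == 1) ? Z : Z / 2;
    if (train) b.in = in;
    rmat out;
    if (b.k == 1) {
      out = in * P->W[i];
      out.each_row() += P->Bv[i];
    } else {
      int zc = chunk_slices(b.Xo, b.Yo, b.Zo, 27 * b.Cin);
      if (train && zc >= b.Zo) {
        // single chunk: keep the im2col buffer for the backward pass
        im2col_chunk(in, X, Y, Z, 3, b.stride, b.Xo, b.Yo, 0, b.Zo, b.colcache);
        out = b.colcache * P->W[i];
      } else {
        out.set_size((size_t)b.Xo * b.Yo * b.Zo, b.Cout);
        rmat col;
        for (int z0 = 0; z0 < b.Zo; z0 += zc) {
          int z1 = std::min(b.Zo, z0 + zc);
          im2col_chunk(in, X, Y, Z, 3, b.stride, b.Xo, b.Yo, z0, z1, col);
          out.rows((size_t)z0 * b.Xo * b.Yo,
                   (size_t)z1 * b.Xo * b.Yo - 1) = col * P->W[i];
        }
      }
      out.each_row() += P->Bv[i];
    }
    if (b.norm) {
      rrowvec m = arma::mean(out, 0);
      rrowvec v = arma::mean(arma::square(out), 0) - arma::square(m);
      v.transform([](real x) { return x > 0 ? x : (real)0; });
      b.invstd = 1.0 / arma::sqrt(v + IN_EPS);
      out.each_row() -= m;
      out.each_row() %= b.invstd;
      if (train) b.xhat = out;
      out.each_row() %= P->Nrm[i].col(0).t();
      out.each_row() += P->Nrm[i].col(1).t();
    }
    if (b.act) {
      real s = c.slope;
      out.transform([s](real x) { return x > 0 ? x : s * x; });
      if (train) b.y = out;
    }
    return out;
  }

  rmat block_bwd(int i, rmat d, bool need_din = true) {
    Block& b = B[i];
    if (b.act) {
      real s = c.slope;
      rmat f = b.y;
      f.transform([s](real x) { return x > 0 ? (real)1 : s; });
      d %= f;
    }
    if (b.norm) {
      G->Nrm[i].col(0) += arma::sum(d % b.xhat, 0).t();
      G->Nrm[i].col(1) += arma::sum(d, 0).t();
      d.each_row() %= P->Nrm[i].col(0).t();  // dxhat
      real N = (real)d.n_rows;
      rrowvec sd = arma::sum(d, 0);
      rrowvec sdx = arma::sum(d % b.xhat, 0);
      d *= N;
      d.each_row() -= sd;
      rmat t2 = b.xhat;
      t2.each_row() %= sdx;
      d -= t2;
      d.each_row() %= (b.invstd / N);
    }
    G->Bv[i] += arma::sum(d, 0);
    rmat din;
    if (b.k == 1) {
      G->W[i] += b.in.t() * d;
      if (need_din) din = d * P->W[i].t();
    } else if (b.colcache.n_elem > 0) {
      G->W[i] += b.colcache.t() * d;
      if (need_din) {
        din.zeros(b.in.n_rows, b.Cin);
        rmat dcol = d * P->W[i].t();
        col2im_chunk(dcol, b.Xi, b.Yi, b.Zi, 3, b.stride, b.Xo, b.Yo,
                     0, b.Zo, din);
      }
    } else {
      if (need_din) din.zeros(b.in.n_rows, b.Cin);
      int zc = chunk_slices(b.Xo, b.Yo, b.Zo, 27 * b.Cin);
      rmat col;
      for (int z0 = 0; z0 < b.Zo; z0 += zc) {
        int z1 = std::min(b.Zo, z0 + zc);
        im2col_chunk(b.in, b.Xi, b.Yi, b.Zi, 3, b.stride, b.Xo, b.Yo, z0, z1, col);
        rmat dr = d.rows((size_t)z0 * b.Xo * b.Yo, (size_t)z1 * b.Xo * b.Yo - 1);
        G->W[i] += col.t() * dr;
        if (need_din) {
          rmat dcol = dr * P->W[i].t();
          col2im_chunk(dcol, b.Xi, b.Yi, b.Zi, 3, b.stride, b.Xo, b.Yo, z0, z1, din);
        }
      }
    }
    b.in.reset(); b.xhat.reset(); b.y.reset(); b.colcache.reset();
    return din;
  }

  rmat dropout_fwd(int l, rmat x) {
    if (!train || c.dropout <= 0) return x;
    std::uniform_real_distribution<double> U(0.0, 1.0);
    rmat m(x.n_rows, x.n_cols);
    real keep = 1 - c.dropout;
    for (size_t i = 0; i < m.n_elem; ++i)
      m(i) = (U(rng) < keep) ? 1 / keep : (real)0;
    dropmask[l] = m;
    return x % m;
  }

  rmat dropout_bwd(int l, rmat d) {
    if (!train || c.dropout <= 0) return d;
    d %= dropmask[l];
    dropmask[l].reset();
    return d;
  }

  // nearest-neighbour upsampling index (factor f): (X,Y,Z) -> (fX,fY,fZ)
  static uvec up_index(int X, int Y, int Z, int f) {
    uvec idx((size_t)X * Y * Z * f * f * f);
    size_t r = 0;
    for (int z = 0; z < Z * f; ++z)
      for (int y = 0; y < Y * f; ++y)
        for (int x = 0; x < X * f; ++x, ++r)
          idx[r] = (size_t)(x / f) +
                   (size_t)X * ((size_t)(y / f) + (size_t)Y * (z / f));
    return idx;
  }

  static rmat up_gather(const rmat& in, const uvec& idx) {
    rmat out(idx.n_elem, in.n_cols);
    for (size_t c = 0; c < in.n_cols; ++c) {
      real* dst = out.colptr(c);
      const real* src = in.colptr(c);
      for (size_t r = 0; r < idx.n_elem; ++r) dst[r] = src[idx[r]];
    }
    return out;
  }

  static rmat up_bwd(const rmat& dout, const uvec& idx, size_t nin) {
    rmat din(nin, dout.n_cols, arma::fill::zeros);
    for (size_t c = 0; c < dout.n_cols; ++c) {
      real* dst = din.colptr(c);
      const real* src = dout.colptr(c);
      for (size_t r = 0; r < idx.n_elem; ++r) dst[idx[r]] += src[r];
    }
    return din;
  }

  // block index helpers (creation order in build_blocks)
  int enc_base(int l) const { return 3 * l; }
  int dec_base(int j) const { return 3 * (c.depth + 1) + 3 * j; }
  int seg_idx(int l) const { return 3 * (c.depth + 1) + 3 * c.depth + (2 - l); }

  // Full forward; x is (nvox x inC) at dims (X,Y,Z). Returns logits.
  rmat forward(const rmat& x, int X, int Y, int Z) {
    skip.assign(c.depth + 1, rmat());
    dims.assign(3 * (c.depth + 1), 0);
    int dX = X, dY = Y, dZ = Z;
    rmat h = block_fwd(0, x, dX, dY, dZ);
    {
      rmat a = block_fwd(1, h, dX, dY, dZ);
      a = dropout_fwd(0, std::move(a));
      a = block_fwd(2, a, dX, dY, dZ);
      skip[0] = h + a;
    }
    dims[0] = dX; dims[1] = dY; dims[2] = dZ;
    for (int l = 1; l <= c.depth; ++l) {
      int bi = enc_base(l);
      rmat d0 = block_fwd(bi, skip[l - 1], dX, dY, dZ);
      dX /= 2; dY /= 2; dZ /= 2;
      rmat a = block_fwd(bi + 1, d0, dX, dY, dZ);
      a = dropout_fwd(l, std::move(a));
      a = block_fwd(bi + 2, a, dX, dY, dZ);
      skip[l] = d0 + a;
      dims[3 * l] = dX; dims[3 * l + 1] = dY; dims[3 * l + 2] = dZ;
    }
    rmat u = skip[c.depth];
    rmat seg_total;
    for (int j = 0; j < c.depth; ++j) {
      int l = c.depth - 1 - j;
      int bi = dec_base(j);
      int sX = dims[3 * (l + 1)], sY = dims[3 * (l + 1) + 1],
          sZ = dims[3 * (l + 1) + 2];
      uvec idx = up_index(sX, sY, sZ, 2);
      rmat upd = up_gather(u, idx);
      int uX = dims[3 * l], uY = dims[3 * l + 1], uZ = dims[3 * l + 2];
      rmat v = block_fwd(bi, upd, uX, uY, uZ);
      rmat cat = arma::join_rows(v, skip[l]);
      rmat a = block_fwd(bi + 1, cat, uX, uY, uZ);
      rmat o = block_fwd(bi + 2, a, uX, uY, uZ);
      if (l <= 2) {
        rmat s = block_fwd(seg_idx(l), o, uX, uY, uZ);
        if (l > 0) {
          uvec sidx = up_index(uX, uY, uZ, 1 << l);
          s = up_gather(s, sidx);
        }
        if (seg_total.n_elem == 0) seg_total = std::move(s);
        else seg_total += s;
      }
      u = std::move(o);
    }
    return seg_total;
  }

  rmat& dec_skip_grad(int l) {
    if (skip_grad.empty()) skip_grad.assign(c.depth + 1, rmat());
    if (skip_grad[l].n_elem == 0)
      skip_grad[l].zeros(skip[l].n_rows, skip[l].n_cols);
    return skip_grad[l];
  }

  // Backward from dlogits; accumulates into G.
  void backward(const rmat& dlogits) {
    rmat du;  // grad wrt decoder output o_l, starting at l = 0
    for (int l = 0; l < c.depth; ++l) {
      int j = c.depth - 1 - l;
      int bi = dec_base(j);
      int uX = dims[3 * l], uY = dims[3 * l + 1], uZ = dims[3 * l + 2];
      rmat do_l;
      if (l == 0) {
        do_l = block_bwd(seg_idx(0), dlogits);
      } else {
        do_l = std::move(du);
        if (l <= 2) {
          uvec sidx = up_index(uX, uY, uZ, 1 << l);
          rmat dseg = up_bwd(dlogits, sidx, (size_t)uX * uY * uZ);
          do_l += block_bwd(seg_idx(l), std::move(dseg));
        }
      }
      rmat dcat = block_bwd(bi + 1, block_bwd(bi + 2, std::move(do_l)));
      int Cl = B[bi].Cout;
      rmat dv = dcat.cols(0, Cl - 1);
      rmat dskip = dcat.cols(Cl, 2 * Cl - 1);
      dec_skip_grad(l) += dskip;
      rmat dupd = block_bwd(bi, std::move(dv));
      int sX = dims[3 * (l + 1)], sY = dims[3 * (l + 1) + 1],
          sZ = dims[3 * (l + 1) + 2];
      uvec idx = up_index(sX, sY, sZ, 2);
      du = up_bwd(dupd, idx, (size_t)sX * sY * sZ);
      if (l == c.depth - 1) dec_skip_grad(c.depth) += du;
    }
    for (int l = c.depth; l >= 1; --l) {
      int bi = enc_base(l);
      rmat ds = std::move(skip_grad[l]);
      rmat da = block_bwd(bi + 2, ds);
      da = dropout_bwd(l, std::move(da));
      da = block_bwd(bi + 1, std::move(da));
      rmat dd = ds + da;
      skip_grad[l - 1] += block_bwd(bi, std::move(dd));
    }
    {
      rmat ds = std::move(skip_grad[0]);
      rmat da = block_bwd(2, ds);
      da = dropout_bwd(0, std::move(da));
      da = block_bwd(1, std::move(da));
      rmat dh = ds + da;
      block_bwd(0, std::move(dh), false);
    }
  }
};

// ---- activations + losses --------------------------------------------------

static rmat apply_activation(const rmat& logits, bool softmax) {
  if (!softmax) {
    rmat p = logits;
    p.transform([](real z) { return (real)(1.0 / (1.0 + std::exp(-(double)z))); });
    return p;
  }
  rmat p = logits;
  rcol mx = arma::max(p, 1);
  p.each_col() -= mx;
  p = arma::exp(p);
  rcol s = arma::sum(p, 1);
  p.each_col() /= s;
  return p;
}

static const double DICE_EPS = 1e-5;
static const real LOG_CLAMP = (real)1e-7;

// loss value + gradient wrt logits (double accumulators for the sums)
static double loss_and_dlogits(const rmat& logits, const rmat& target,
                               bool softmax, const std::string& loss,
                               const rrowvec& w, rmat& dlogits) {
  const double N = (double)logits.n_rows;
  rmat p = apply_activation(logits, softmax);
  if (loss == "dice") {
    const int C = p.n_cols;
    dlogits.set_size(p.n_rows, C);
    double L = 1.0;
    for (int cc = 0; cc < C; ++cc) {
      double num = 2.0 * arma::dot(arma::conv_to<arma::vec>::from(p.col(cc)),
                                   arma::conv_to<arma::vec>::from(target.col(cc)))
                   + DICE_EPS;
      double den = arma::accu(arma::conv_to<arma::vec>::from(p.col(cc))) +
                   arma::accu(arma::conv_to<arma::vec>::from(target.col(cc))) +
                   DICE_EPS;
      L -= (num / den) / C;
      // d(num/den)/dp = (2 t den - num) / den^2
      dlogits.col(cc) =
          -((real)(2.0 / den)) * target.col(cc) / (real)C +
          arma::ones<rcol>(p.n_rows) * (real)(num / (den * den) / C);
    }
    dlogits %= p % (1 - p);  // through sigmoid
    return L;
  }
  // categorical cross-entropy (optionally class-weighted), softmax head
  rmat pc = p;
  pc.transform([](real x) { return x < LOG_CLAMP ? LOG_CLAMP : x; });
  rcol wv(p.n_rows, arma::fill::ones);
  if (loss == "wcce") wv = target * w.t();  // one-hot picks the class weight
  rmat lt = arma::log(pc);
  double L = 0;
  {
    rcol rowsum = arma::sum(target % lt, 1);
    arma::vec rs = arma::conv_to<arma::vec>::from(rowsum % wv);
    L = -arma::accu(rs) / N;
  }
  dlogits = p;
  dlogits.each_col() %= wv;
  rmat t2 = target;
  t2.each_col() %= wv;
  dlogits -= t2;
  dlogits /= (real)N;
  return L;
}

// ---- exported entry points -------------------------------------------------

static rmat as_feature_mat(const NumericVector& x, int X, int Y, int Z, int C) {
  if ((R_xlen_t)X * Y * Z * C != x.size())
    stop("input array size does not match dims/channels");
  rmat m((size_t)X * Y * Z, C);
  const double* p = x.begin();
  for (size_t i = 0; i < m.n_elem; ++i) m(i) = (real)p[i];
  return m;
}

// [[Rcpp::export]]
NumericVector cpp_unet_forward(List cfg, NumericVector params, NumericVector x,
                               IntegerVector dims) {
  UCfg c = parse_cfg(cfg);
  int X = dims[0], Y = dims[1], Z = dims[2];
  std::vector<Block> B = build_blocks(c);
  Params P = unpack_params(c, B, params);
  UNet net(c, P, nullptr, false, 0);
  rmat logits = net.forward(as_feature_mat(x, X, Y, Z, c.inC), X, Y, Z);
  rmat p = apply_activation(logits, c.softmax);
  NumericVector out(p.n_elem);
  for (size_t i = 0; i < p.n_elem; ++i) out[i] = (double)p(i);
  out.attr("dim") = IntegerVector::create(X, Y, Z, c.outC);
  return out;
}

// [[Rcpp::export]]
List cpp_unet_loss_grad(List cfg, NumericVector params, NumericVector x,
                        IntegerVector dims, NumericVector target,
                        std::string loss, NumericVector class_weights,
                        int seed, bool train) {
  UCfg c = parse_cfg(cfg);
  int X = dims[0], Y = dims[1], Z = dims[2];
  std::vector<Block> B = build_blocks(c);
  Params P = unpack_params(c, B, params);
  Grads G = zero_grads(B);
  UNet net(c, P, &G, true, (uint64_t)seed);
  if (!train) net.c.dropout = 0;  // caches stay on; dropout off in eval
  rmat xm = as_feature_mat(x, X, Y, Z, c.inC);
  rmat tm = as_feature_mat(target, X, Y, Z, c.outC);
  rmat logits = net.forward(xm, X, Y, Z);
  rrowvec w(c.outC, arma::fill::ones);
  if (class_weights.size() == (R_xlen_t)c.outC)
    for (int i = 0; i < c.outC; ++i) w(i) = (real)class_weights[i];
  rmat dlogits;
  double L = loss_and_dlogits(logits, tm, c.softmax, loss, w, dlogits);
  net.backward(dlogits);
  R_xlen_t ntot = params.size();
  NumericVector g(ntot);
  size_t off = 0;
  for (size_t i = 0; i < B.size(); ++i) {
    for (size_t j = 0; j < G.W[i].n_elem; ++j) g[off + j] = (double)G.W[i](j);
    off += G.W[i].n_elem;
    for (size_t j = 0; j < G.Bv[i].n_elem; ++j) g[off + j] = (double)G.Bv[i](j);
    off += G.Bv[i].n_elem;
    if (B[i].norm) {
      for (size_t j = 0; j < G.Nrm[i].n_elem; ++j)
        g[off + j] = (double)G.Nrm[i](j);
      off += G.Nrm[i].n_elem;
    }
  }
  return List::create(_["loss"] = L, _["grad"] = g);
}
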
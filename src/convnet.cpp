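// Compact 3D U-Net engine for 3-class voxel segmentation.
//
// Feature maps live as arma::fmat (channels x voxels), voxels in the col-major
// order of an R (Z,Y,X) array (z fastest). 3^3 convolutions run as chunked
// im2col + SGEMM; downsampling is a stride-2 conv with a residual projection
// of the 2x average-pooled input; upsampling is a learned 2^3 stride-2
// transposed conv whose output is trimmed on the trailing (high-index) edges
// to match the encoder map before skip concatenation, so the network accepts
// cuboids of any extent and returns logits of the same extent.
//
// Forward caches the padded layer inputs and post-ReLU activations in a
// heap-held struct (external pointer); backward recomputes im2col buffers
// from the cached padded inputs rather than storing them.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <map>
#include <string>
#include <vector>

using namespace Rcpp;
typedef arma::fmat FM;
typedef arma::fvec FV;

struct D3 {
  int z, y, x;
  R_xlen_t n() const { return (R_xlen_t)z * y * x; }
};

struct NetCache {
  int L, base;
  D3 din;
  std::map<std::string, FM> M;   // cached activations / padded inputs
  std::map<std::string, D3> D;   // their spatial dims
  std::vector<D3> ed;            // encoder dims per level (1-based index)
};

static D3 halfdim(D3 d) { return D3{(d.z + 1) / 2, (d.y + 1) / 2, (d.x + 1) / 2}; }

// replicate ("clamp") padding by one voxel: border cells copy the nearest
// edge voxel, so convolution inputs look the same at crop edges, volume
// edges and interior cuts - no zero-pad distribution shift
static FM pad1(const FM &X, D3 d) {
  int C = X.n_rows;
  D3 dp{d.z + 2, d.y + 2, d.x + 2};
  FM P(C, dp.n());
  for (int x = 0; x < dp.x; ++x) {
    int xs = std::min(std::max(x - 1, 0), d.x - 1);
    for (int y = 0; y < dp.y; ++y) {
      int ys = std::min(std::max(y - 1, 0), d.y - 1);
      R_xlen_t src = (R_xlen_t)d.z * (ys + (R_xlen_t)d.y * xs);
      R_xlen_t dst = (R_xlen_t)dp.z * (y + (R_xlen_t)dp.y * x);
      P.cols(dst + 1, dst + d.z) = X.cols(src, src + d.z - 1);
      P.col(dst) = X.col(src);
      P.col(dst + d.z + 1) = X.col(src + d.z - 1);
    }
  }
  return P;
}

// fold the gradient of the replicate-padded ring back onto the clamped
// interior sources (in padded coordinates), so that a subsequent interior
// extraction yields the full gradient
static void fold_pad1(FM &dP, D3 d) {
  D3 dp{d.z + 2, d.y + 2, d.x + 2};
  for (int x = 0; x < dp.x; ++x) {
    int xs = std::min(std::max(x - 1, 0), d.x - 1) + 1;
    for (int y = 0; y < dp.y; ++y) {
      int ys = std::min(std::max(y - 1, 0), d.y - 1) + 1;
      bool face_xy = (x != xs) || (y != ys);
      R_xlen_t col0 = (R_xlen_t)dp.z * (y + (R_xlen_t)dp.y * x);
      R_xlen_t tgt0 = (R_xlen_t)dp.z * (ys + (R_xlen_t)dp.y * xs);
      if (face_xy)
        dP.cols(tgt0 + 1, tgt0 + d.z) += dP.cols(col0 + 1, col0 + d.z);
      // z end caps (source z rows 1 and d.z in padded coords)
      dP.col(tgt0 + 1) += dP.col(col0);
      dP.col(tgt0 + d.z) += dP.col(col0 + d.z + 1);
    }
  }
}

// im2col for a 3^3 kernel over output x-slab [xa, xb); Col rows are ordered
// ci + C*koff with koff = dz + 3*dy + 9*dx, matching the permuted weights.
static void im2col3(const FM &P, D3 dp, int stride, D3 dout, int xa, int xb,
                    FM &Col) {
  int C = P.n_rows;
  R_xlen_t plane = (R_xlen_t)dout.z * dout.y;
  for (int dx = 0; dx < 3; ++dx)
    for (int dy = 0; dy < 3; ++dy)
      for (int dz = 0; dz < 3; ++dz) {
        int koff = dz + 3 * dy + 9 * dx;
        int r0 = koff * C;
        for (int xo = xa; xo < xb; ++xo)
          for (int yo = 0; yo < dout.y; ++yo) {
            R_xlen_t cbase = (R_xlen_t)dout.z * yo + plane * (xo - xa);
            R_xlen_t pbase = (R_xlen_t)(dz) + (R_xlen_t)dp.z *
                ((yo * stride + dy) + (R_xlen_t)dp.y * (xo * stride + dx));
            if (stride == 1) {
              Col.submat(r0, cbase, r0 + C - 1, cbase + dout.z - 1) =
                  P.cols(pbase, pbase + dout.z - 1);
            } else {
              for (int zo = 0; zo < dout.z; ++zo)
                Col.col(cbase + zo).rows(r0, r0 + C - 1) =
                    P.col(pbase + (R_xlen_t)zo * stride);
            }
          }
      }
}

static void col2im3_add(const FM &Col, FM &dP, D3 dp, int stride, D3 dout,
                        int xa, int xb) {
  int C = dP.n_rows;
  R_xlen_t plane = (R_xlen_t)dout.z * dout.y;
  for (int dx = 0; dx < 3; ++dx)
    for (int dy = 0; dy < 3; ++dy)
      for (int dz = 0; dz < 3; ++dz) {
        int koff = dz + 3 * dy + 9 * dx;
        int r0 = koff * C;
        for (int xo = xa; xo < xb; ++xo)
          for (int yo = 0; yo < dout.y; ++yo) {
            R_xlen_t cbase = (R_xlen_t)dout.z * yo + plane * (xo - xa);
            R_xlen_t pbase = (R_xlen_t)(dz) + (R_xlen_t)dp.z *
                ((yo * stride + dy) + (R_xlen_t)dp.y * (xo * stride + dx));
            if (stride == 1) {
              dP.cols(pbase, pbase + dout.z - 1) +=
                  Col.submat(r0, cbase, r0 + C - 1, cbase + dout.z - 1);
            } else {
              for (int zo = 0; zo < dout.z; ++zo)
                dP.col(pbase + (R_xlen_t)zo * stride) +=
                    Col.col(cbase + zo).rows(r0, r0 + C - 1);
            }
          }
      }
}

static int conv_chunk_planes(D3 dout, int C) {
  double bytes_per_plane = 27.0 * C * 4.0 * dout.z * dout.y;
  int nx = (int)std::max(1.0, std::floor(96e6 / bytes_per_plane));
  return std::min(nx, dout.x);
}

static FM conv3_fwd(const FM &P, D3 dp, const FM &Wm, const FV &b, int stride,
                    D3 &dout) {
  int C = P.n_rows, Cout = Wm.n_cols;
  dout = D3{(dp.z - 3) / stride + 1, (dp.y - 3) / stride + 1,
            (dp.x - 3) / stride + 1};
  FM OUT(Cout, dout.n());
  int nx = conv_chunk_planes(dout, C);
  FM Col(27 * C, (R_xlen_t)dout.z * dout.y * nx);
  for (int xa = 0; xa < dout.x; xa += nx) {
    int xb = std::min(xa + nx, dout.x);
    R_xlen_t ncol = (R_xlen_t)dout.z * dout.y * (xb - xa);
    im2col3(P, dp, stride, dout, xa, xb, Col);
    R_xlen_t c0 = (R_xlen_t)dout.z * dout.y * xa;
    OUT.cols(c0, c0 + ncol - 1) = Wm.t() * Col.head_cols(ncol);
  }
  OUT.each_col() += b;
  return OUT;
}

// returns dP; accumulates dWm, db
static FM conv3_bwd(const FM &P, D3 dp, const FM &Wm, int stride, D3 dout,
                    const FM &dOUT, FM &dWm, FV &db) {
  int C = P.n_rows;
  FM dP(C, dp.n(), arma::fill::zeros);
  dWm.zeros(Wm.n_rows, Wm.n_cols);
  db = arma::sum(dOUT, 1);
  int nx = conv_chunk_planes(dout, C);
  FM Col(27 * C, (R_xlen_t)dout.z * dout.y * nx);
  for (int xa = 0; xa < dout.x; xa += nx) {
    int xb = std::min(xa + nx, dout.x);
    R_xlen_t ncol = (R_xlen_t)dout.z * dout.y * (xb - xa);
    im2col3(P, dp, stride, dout, xa, xb, Col);
    R_xlen_t c0 = (R_xlen_t)dout.z * dout.y * xa;
    const FM dsub = dOUT.cols(c0, c0 + ncol - 1);
    dWm += Col.head_cols(ncol) * dsub.t();
    FM dCol = Wm * dsub;
    col2im3_add(dCol, dP, dp, stride, dout, xa, xb);
  }
  return dP;
}

// learned 2x upsampling: 2^3 kernel, stride 2; output dims exactly 2*din
static FM upconv2_fwd(const FM &X, D3 din, const FM &Wm, const FV &b, D3 &dout) {
  int Cin = X.n_rows, Cout = Wm.n_cols;
  dout = D3{2 * din.z, 2 * din.y, 2 * din.x};
  FM OUT(Cout, dout.n());
  for (int dx = 0; dx < 2; ++dx)
    for (int dy = 0; dy < 2; ++dy)
      for (int dz = 0; dz < 2; ++dz) {
        int koff = dz + 2 * dy + 4 * dx;
        FM T = Wm.rows(koff * Cin, (koff + 1) * Cin - 1).t() * X;  // Cout x Nin
        for (int x = 0; x < din.x; ++x)
          for (int y = 0; y < din.y; ++y) {
            R_xlen_t src = (R_xlen_t)din.z * (y + (R_xlen_t)din.y * x);
            R_xlen_t dst = (R_xlen_t)(dz) + (R_xlen_t)dout.z *
                ((2 * y + dy) + (R_xlen_t)dout.y * (2 * x + dx));
            for (int z = 0; z < din.z; ++z)
              OUT.col(dst + 2 * (R_xlen_t)z) = T.col(src + z);
          }
      }
  OUT.each_col() += b;
  return OUT;
}

static FM upconv2_bwd(const FM &X, D3 din, const FM &Wm, const FM &dOUT,
                      D3 dout, FM &dWm, FV &db) {
  int Cin = X.n_rows, Cout = Wm.n_cols;
  FM dX(Cin, din.n(), arma::fill::zeros);
  dWm.zeros(Wm.n_rows, Wm.n_cols);
  db = arma::sum(dOUT, 1);
  FM dT(Cout, din.n());
  for (int dx = 0; dx < 2; ++dx)
    for (int dy = 0; dy < 2; ++dy)
      for (int dz = 0; dz < 2; ++dz) {
        int koff = dz + 2 * dy + 4 * dx;
        for (int x = 0; x < din.x; ++x)
          for (int y = 0; y < din.y; ++y) {
            R_xlen_t src = (R_xlen_t)din.z * (y + (R_xlen_t)din.y * x);
            R_xlen_t dst = (R_xlen_t)(dz) + (R_xlen_t)dout.z *
                ((2 * y + dy) + (R_xlen_t)dout.y * (2 * x + dx));
            for (int z = 0; z < din.z; ++z)
              dT.col(src + z) = dOUT.col(dst + 2 * (R_xlen_t)z);
          }
        dWm.rows(koff * Cin, (koff + 1) * Cin - 1) += X * dT.t();
        dX += Wm.rows(koff * Cin, (koff + 1) * Cin - 1) * dT;
      }
  return dX;
}

// 2x average pooling with edge clamping; output dims = ceil(din/2)
static FM avgpool2_fwd(const FM &X, D3 din, D3 &dout) {
  int C = X.n_rows;
  dout = halfdim(din);
  FM OUT(C, dout.n(), arma::fill::zeros);
  for (int xo = 0; xo < dout.x; ++xo)
    for (int yo = 0; yo < dout.y; ++yo)
      for (int zo = 0; zo < dout.z; ++zo) {
        R_xlen_t dst = (R_xlen_t)zo + (R_xlen_t)dout.z *
                       (yo + (R_xlen_t)dout.y * xo);
        int cnt = 0;
        for (int dx = 0; dx < 2 && 2 * xo + dx < din.x; ++dx)
          for (int dy = 0; dy < 2 && 2 * yo + dy < din.y; ++dy)
            for (int dz = 0; dz < 2 && 2 * zo + dz < din.z; ++dz) {
              R_xlen_t src = (R_xlen_t)(2 * zo + dz) + (R_xlen_t)din.z *
                  ((2 * yo + dy) + (R_xlen_t)din.y * (2 * xo + dx));
              OUT.col(dst) += X.col(src);
              ++cnt;
            }
        OUT.col(dst) /= (float)cnt;
      }
  return OUT;
}

static FM avgpool2_bwd(const FM &dOUT, D3 din, D3 dout, int C) {
  FM dX(C, din.n(), arma::fill::zeros);
  for (int xo = 0; xo < dout.x; ++xo)
    for (int yo = 0; yo < dout.y; ++yo)
      for (int zo = 0; zo < dout.z; ++zo) {
        R_xlen_t dst = (R_xlen_t)zo + (R_xlen_t)dout.z *
                       (yo + (R_xlen_t)dout.y * xo);
        int cnt = 0;
        for (int dx = 0; dx < 2 && 2 * xo + dx < din.x; ++dx)
          for (int dy = 0; dy < 2 && 2 * yo + dy < din.y; ++dy)
            for (int dz = 0; dz < 2 && 2 * zo + dz < din.z; ++dz)
              ++cnt;
        FV g = dOUT.col(dst) / (float)cnt;
        for (int dx = 0; dx < 2 && 2 * xo + dx < din.x; ++dx)
          for (int dy = 0; dy < 2 && 2 * yo + dy < din.y; ++dy)
            for (int dz = 0; dz < 2 && 2 * zo + dz < din.z; ++dz) {
              R_xlen_t src = (R_xlen_t)(2 * zo + dz) + (R_xlen_t)din.z *
                  ((2 * yo + dy) + (R_xlen_t)din.y * (2 * xo + dx));
              dX.col(src) += g;
            }
      }
  return dX;
}

// trailing-edge trim of an upsampled map down to the encoder dims
static FM crop_to(const FM &X, D3 din, D3 dto) {
  FM OUT(X.n_rows, dto.n());
  for (int x = 0; x < dto.x; ++x)
    for (int y = 0; y < dto.y; ++y) {
      R_xlen_t src = (R_xlen_t)din.z * (y + (R_xlen_t)din.y * x);
      R_xlen_t dst = (R_xlen_t)dto.z * (y + (R_xlen_t)dto.y * x);
      OUT.cols(dst, dst + dto.z - 1) = X.cols(src, src + dto.z - 1);
    }
  return OUT;
}

static FM uncrop_to(const FM &dOUT, D3 dto, D3 din) {
  FM dX(dOUT.n_rows, din.n(), arma::fill::zeros);
  for (int x = 0; x < dto.x; ++x)
    for (int y = 0; y < dto.y; ++y) {
      R_xlen_t src = (R_xlen_t)dto.z * (y + (R_xlen_t)dto.y * x);
      R_xlen_t dst = (R_xlen_t)din.z * (y + (R_xlen_t)din.y * x);
      dX.cols(dst, dst + dto.z - 1) = dOUT.cols(src, src + dto.z - 1);
    }
  return dX;
}

// ---- parameter marshalling -------------------------------------------------

// R weight array (k,k,k,Cin,Cout) -> fmat (k^3*Cin x Cout), row = ci + Cin*koff
static FM weight_to_fmat(const NumericVector &Wr, int kk, int Cin, int Cout) {
  FM Wm(kk * Cin, Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int koff = 0; koff < kk; ++koff)
        Wm(ci + Cin * koff, co) =
            (float)Wr[koff + (R_xlen_t)kk * ci + (R_xlen_t)kk * Cin * co];
  return Wm;
}

static NumericVector fmat_to_weight(const FM &Wm, int kk, int Cin, int Cout,
                                    SEXP dimtmpl) {
  NumericVector Wr((R_xlen_t)kk * Cin * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int koff = 0; koff < kk; ++koff)
        Wr[koff + (R_xlen_t)kk * ci + (R_xlen_t)kk * Cin * co] =
            Wm(ci + Cin * koff, co);
  Wr.attr("dim") = dimtmpl;
  return Wr;
}

struct ParamSet {
  std::map<std::string, FM> W;
  std::map<std::string, FV> b;
  std::map<std::string, int> kk, cin, cout;
  List src;
};

static void load_param(ParamSet &ps, const List &params, const std::string &nm,
                       int kk, int Cin, int Cout) {
  NumericVector Wr = params[nm + "_W"];
  NumericVector br = params[nm + "_b"];
  if ((int)Wr.size() != kk * Cin * Cout)
    stop("parameter %s_W has wrong size", nm.c_str());
  ps.W[nm] = weight_to_fmat(Wr, kk, Cin, Cout);
  ps.b[nm] = FV(Cout);
  for (int i = 0; i < Cout; ++i) ps.b[nm](i) = (float)br[i];
  ps.kk[nm] = kk; ps.cin[nm] = Cin; ps.cout[nm] = Cout;
}

static ParamSet load_params(const List &params, int L, int base) {
  ParamSet ps;
  ps.src = params;
  int c1 = base;
  load_param(ps, params, "stem1", 27, 1, c1);
  load_param(ps, params, "stem2", 27, c1, c1);
  for (int l = 2; l <= L; ++l) {
    int cp = base << (l - 2), cl = base << (l - 1);
    load_param(ps, params, "down" + std::to_string(l), 27, cp, cl);
    load_param(ps, params, "proj" + std::to_string(l), 1, cp, cl);
    load_param(ps, params, "conv" + std::to_string(l), 27, cl, cl);
  }
  for (int l = L - 1; l >= 1; --l) {
    int cl = base << (l - 1), cd = base << l;
    load_param(ps, params, "up" + std::to_string(l), 8, cd, cl);
    load_param(ps, params, "dec" + std::to_string(l), 27, 2 * cl, cl);
  }
  load_param(ps, params, "head", 1, c1, 3);
  return ps;
}

static void relu_(FM &X) { X.transform([](float v) { return v > 0 ? v : 0.0f; }); }

// ---- forward ---------------------------------------------------------------

// [[Rcpp::export]]
List cpp_net_forward(NumericVector x, IntegerVector dims, List params,
                     int n_levels, int base_channels, bool want_cache) {
  D3 din{dims[0], dims[1], dims[2]};
  ParamSet ps = load_params(params, n_levels, base_channels);
  NetCache *C = new NetCache();
  C->L = n_levels; C->base = base_channels; C->din = din;
  C->ed.resize(n_levels + 1);
  C->ed[1] = din;

  FM X0(1, din.n());
  for (R_xlen_t i = 0; i < din.n(); ++i) X0(0, i) = (float)x[i];

  // encoder
  FM P = pad1(X0, din);
  if (want_cache) { C->M["P_stem1"] = P; C->D["P_stem1"] = din; }
  D3 d1;
  FM A = conv3_fwd(P, D3{din.z + 2, din.y + 2, din.x + 2}, ps.W["stem1"],
                   ps.b["stem1"], 1, d1);
  relu_(A);
  if (want_cache) C->M["O_stem1"] = A;
  FM Pa = pad1(A, din);
  if (want_cache) C->M["P_stem2"] = Pa;
  FM E = conv3_fwd(Pa, D3{din.z + 2, din.y + 2, din.x + 2}, ps.W["stem2"],
                   ps.b["stem2"], 1, d1);
  relu_(E);
  if (want_cache) C->M["E1"] = E;

  std::vector<FM> enc(n_levels + 1);
  enc[1] = E;
  D3 dcur = din;
  for (int l = 2; l <= n_levels; ++l) {
    std::string sl = std::to_string(l);
    FM Pe = pad1(enc[l - 1], dcur);
    if (want_cache) C->M["P_down" + sl] = Pe;
    D3 dl;
    FM DN = conv3_fwd(Pe, D3{dcur.z + 2, dcur.y + 2, dcur.x + 2},
                      ps.W["down" + sl], ps.b["down" + sl], 2, dl);
    D3 dpool;
    FM PP = avgpool2_fwd(enc[l - 1], dcur, dpool);
    if (want_cache) C->M["PP" + sl] = PP;
    FM PR = ps.W["proj" + sl].t() * PP;
    PR.each_col() += ps.b["proj" + sl];
    FM H = DN + PR;
    relu_(H);
    if (want_cache) C->M["H" + sl] = H;
    FM Ph = pad1(H, dl);
    if (want_cache) C->M["P_conv" + sl] = Ph;
    D3 dl2;
    FM El = conv3_fwd(Ph, D3{dl.z + 2, dl.y + 2, dl.x + 2}, ps.W["conv" + sl],
                      ps.b["conv" + sl], 1, dl2);
    relu_(El);
    if (want_cache) C->M["E" + sl] = El;
    enc[l] = El;
    dcur = dl;
    C->ed[l] = dl;
  }

  // decoder
  FM Xd = enc[n_levels];
  D3 dd = C->ed[n_levels];
  for (int l = n_levels - 1; l >= 1; --l) {
    std::string sl = std::to_string(l);
    if (want_cache) { C->M["DIN_up" + sl] = Xd; C->D["DIN_up" + sl] = dd; }
    D3 dup;
    FM U = upconv2_fwd(Xd, dd, ps.W["up" + sl], ps.b["up" + sl], dup);
    relu_(U);
    if (want_cache) { C->M["U" + sl] = U; C->D["U" + sl] = dup; }
    D3 dto = C->ed[l];
    FM Uc = crop_to(U, dup, dto);
    FM CAT = arma::join_cols(Uc, enc[l]);
    FM Pc = pad1(CAT, dto);
    if (want_cache) C->M["P_dec" + sl] = Pc;
    D3 dtmp;
    Xd = conv3_fwd(Pc, D3{dto.z + 2, dto.y + 2, dto.x + 2}, ps.W["dec" + sl],
                   ps.b["dec" + sl], 1, dtmp);
    relu_(Xd);
    if (want_cache) C->M["O_dec" + sl] = Xd;
    dd = dto;
  }

  FM LOG = ps.W["head"].t() * Xd;
  LOG.each_col() += ps.b["head"];

  NumericVector out((R_xlen_t)din.n() * 3);
  for (int c = 0; c < 3; ++c)
    for (R_xlen_t i = 0; i < din.n(); ++i)
      out[i + din.n() * c] = LOG(c, i);
  out.attr("dim") = IntegerVector::create(din.z, din.y, din.x, 3);

  List res;
  res["logits"] = out;
  if (want_cache) {
    XPtr<NetCache> ptr(C, true);
    res["cache"] = ptr;
  } else {
    delete C;
    res["cache"] = R_NilValue;
  }
  return res;
}

// ---- backward --------------------------------------------------------------

// [[Rcpp::export]]
List cpp_net_backward(SEXP cache_ptr, NumericVector dlogits, List params) {
  XPtr<NetCache> C(cache_ptr);
  int L = C->L, base = C->base;
  D3 din = C->din;
  ParamSet ps = load_params(params, L, base);
  List grads;

  FM dLOG(3, din.n());
  for (int c = 0; c < 3; ++c)
    for (R_xlen_t i = 0; i < din.n(); ++i)
      dLOG(c, i) = (float)dlogits[i + din.n() * c];

  // head (1x1)
  const FM &Xhead = C->M["O_dec1"];
  FM dW_head = Xhead * dLOG.t();
  FV db_head = arma::sum(dLOG, 1);
  NumericVector hw = ps.src["head_W"];
  grads["head_W"] = fmat_to_weight(dW_head, 1, base, 3, hw.attr("dim"));
  grads["head_b"] = NumericVector(db_head.begin(), db_head.end());
  FM dX = ps.W["head"] * dLOG;

  std::vector<FM> dE(L + 1);  // grads flowing into encoder outputs

  // decoder backward, shallow to deep
  for (int l = 1; l <= L - 1; ++l) {
    std::string sl = std::to_string(l);
    D3 dto = C->ed[l];
    const FM &Odec = C->M["O_dec" + sl];
    dX %= arma::conv_to<FM>::from(Odec > 0);
    const FM &Pc = C->M["P_dec" + sl];
    FM dWm; FV db;
    D3 dp{dto.z + 2, dto.y + 2, dto.x + 2};
    FM dPc = conv3_bwd(Pc, dp, ps.W["dec" + sl], 1, dto, dX, dWm, db);
    fold_pad1(dPc, dto);
    NumericVector wt = ps.src["dec" + sl + "_W"];
    int cl = base << (l - 1);
    grads["dec" + sl + "_W"] = fmat_to_weight(dWm, 27, 2 * cl, cl, wt.attr("dim"));
    grads["dec" + sl + "_b"] = NumericVector(db.begin(), db.end());
    // un-pad dPc -> dCAT
    FM dCAT(2 * cl, dto.n());
    for (int x = 0; x < dto.x; ++x)
      for (int y = 0; y < dto.y; ++y) {
        R_xlen_t src = 1 + (R_xlen_t)dp.z * ((y + 1) + (R_xlen_t)dp.y * (x + 1));
        R_xlen_t dst = (R_xlen_t)dto.z * (y + (R_xlen_t)dto.y * x);
        dCAT.cols(dst, dst + dto.z - 1) = dPc.cols(src, src + dto.z - 1);
      }
    FM dUc = dCAT.rows(0, cl - 1);
    dE[l] = dCAT.rows(cl, 2 * cl - 1);
    D3 dup = C->D["U" + sl];
    FM dU = uncrop_to(dUc, dto, dup);
    const FM &U = C->M["U" + sl];
    dU %= arma::conv_to<FM>::from(U > 0);
    const FM &DINu = C->M["DIN_up" + sl];
    D3 ddin = C->D["DIN_up" + sl];
    FM dWu; FV dbu;
    FM dXd = upconv2_bwd(DINu, ddin, ps.W["up" + sl], dU, dup, dWu, dbu);
    NumericVector wu = ps.src["up" + sl + "_W"];
    grads["up" + sl + "_W"] = fmat_to_weight(dWu, 8, base << l, cl, wu.attr("dim"));
    grads["up" + sl + "_b"] = NumericVector(dbu.begin(), dbu.end());
    dX = dXd;  // gradient into decoder input at level l+1 (or encoder top)
  }
  dE[L] = dX;

  // encoder backward, deep to shallow
  for (int l = L; l >= 2; --l) {
    std::string sl = std::to_string(l);
    int cp = base << (l - 2), cl = base << (l - 1);
    D3 dl = C->ed[l], dprev = C->ed[l - 1];
    const FM &El = C->M["E" + sl];
    FM dEl = dE[l];
    dEl %= arma::conv_to<FM>::from(El > 0);
    const FM &Ph = C->M["P_conv" + sl];
    FM dWm; FV db;
    D3 dph{dl.z + 2, dl.y + 2, dl.x + 2};
    FM dPh = conv3_bwd(Ph, dph, ps.W["conv" + sl], 1, dl, dEl, dWm, db);
    fold_pad1(dPh, dl);
    NumericVector wt = ps.src["conv" + sl + "_W"];
    grads["conv" + sl + "_W"] = fmat_to_weight(dWm, 27, cl, cl, wt.attr("dim"));
    grads["conv" + sl + "_b"] = NumericVector(db.begin(), db.end());
    FM dH(cl, dl.n());
    for (int x = 0; x < dl.x; ++x)
      for (int y = 0; y < dl.y; ++y) {
        R_xlen_t src = 1 + (R_xlen_t)dph.z * ((y + 1) + (R_xlen_t)dph.y * (x + 1));
        R_xlen_t dst = (R_xlen_t)dl.z * (y + (R_xlen_t)dl.y * x);
        dH.cols(dst, dst + dl.z - 1) = dPh.cols(src, src + dl.z - 1);
      }
    const FM &H = C->M["H" + sl];
    dH %= arma::conv_to<FM>::from(H > 0);
    // strided down-conv branch
    const FM &Pe = C->M["P_down" + sl];
    D3 dpe{dprev.z + 2, dprev.y + 2, dprev.x + 2};
    FM dWd; FV dbd;
    FM dPe = conv3_bwd(Pe, dpe, ps.W["down" + sl], 2, dl, dH, dWd, dbd);
    fold_pad1(dPe, dprev);
    NumericVector wd = ps.src["down" + sl + "_W"];
    grads["down" + sl + "_W"] = fmat_to_weight(dWd, 27, cp, cl, wd.attr("dim"));
    grads["down" + sl + "_b"] = NumericVector(dbd.begin(), dbd.end());
    FM dEprev(cp, dprev.n());
    for (int x = 0; x < dprev.x; ++x)
      for (int y = 0; y < dprev.y; ++y) {
        R_xlen_t src = 1 + (R_xlen_t)dpe.z * ((y + 1) + (R_xlen_t)dpe.y * (x + 1));
        R_xlen_t dst = (R_xlen_t)dprev.z * (y + (R_xlen_t)dprev.y * x);
        dEprev.cols(dst, dst + dprev.z - 1) = dPe.cols(src, src + dprev.z - 1);
      }
    // residual projection branch
    const FM &PP = C->M["PP" + sl];
    FM dWp = PP * dH.t();
    FV dbp = arma::sum(dH, 1);
    NumericVector wp = ps.src["proj" + sl + "_W"];
    grads["proj" + sl + "_W"] = fmat_to_weight(dWp, 1, cp, cl, wp.attr("dim"));
    grads["proj" + sl + "_b"] = NumericVector(dbp.begin(), dbp.end());
    FM dPP = ps.W["proj" + sl] * dH;
    dEprev += avgpool2_bwd(dPP, dprev, halfdim(dprev), cp);
    if (dE[l - 1].n_elem == 0) dE[l - 1] = dEprev; else dE[l - 1] += dEprev;
  }

  // stem backward
  FM dE1 = dE[1];
  const FM &E1 = C->M["E1"];
  dE1 %= arma::conv_to<FM>::from(E1 > 0);
  const FM &Pa = C->M["P_stem2"];
  D3 dp1{din.z + 2, din.y + 2, din.x + 2};
  FM dW2; FV db2;
  FM dPa = conv3_bwd(Pa, dp1, ps.W["stem2"], 1, din, dE1, dW2, db2);
  fold_pad1(dPa, din);
  NumericVector w2 = ps.src["stem2_W"];
  grads["stem2_W"] = fmat_to_weight(dW2, 27, base, base, w2.attr("dim"));
  grads["stem2_b"] = NumericVector(db2.begin(), db2.end());
  FM dA(base, din.n());
  for (int x = 0; x < din.x; ++x)
    for (int y = 0; y < din.y; ++y) {
      R_xlen_t src = 1 + (R_xlen_t)dp1.z * ((y + 1) + (R_xlen_t)dp1.y * (x + 1));
      R_xlen_t dst = (R_xlen_t)din.z * (y + (R_xlen_t)din.y * x);
      dA.cols(dst, dst + din.z - 1) = dPa.cols(src, src + din.z - 1);
    }
  const FM &A = C->M["O_stem1"];
  dA %= arma::conv_to<FM>::from(A > 0);
  const FM &P0 = C->M["P_stem1"];
  FM dW1; FV db1;
  conv3_bwd(P0, dp1, ps.W["stem1"], 1, din, dA, dW1, db1);
  NumericVector w1 = ps.src["stem1_W"];
  grads["stem1_W"] = fmat_to_weight(dW1, 27, 1, base, w1.attr("dim"));
  grads["stem1_b"] = NumericVector(db1.begin(), db1.end());

  return grads;
}
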
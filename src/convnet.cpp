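// Fully convolutional network backend.
//
// Architecture (fixed topology, configurable widths):
//   5 x [3x3 same-padding conv -> leaky ReLU -> 2x2 max pool (floor)]
//   dropout -> 1x1 single-logit conv -> spatial mean logit
// Batch normalisation of the scalar mean logit and the cross-entropy
// loss live on the R side for inference but are computed here inside
// the training step (the batch statistics couple the images of a
// batch).
//
// The input is sparse (nonzero only at nucleus-centre pixels), so the
// first convolution is evaluated by scattering each nonzero pixel
// through the kernel instead of a dense GEMM; layers 2..5 use
// im2col + GEMM. Single precision throughout.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Weights {
    std::vector<fmat> Wm;   // 5 conv kernels as (Cout x 9*Cin)
    std::vector<fvec> b;    // biases
    fvec w6;                // 1x1 classifier (Cprev)
    float b6;
    std::vector<int> cin, cout;
};

Weights unpackWeights(const Rcpp::List& wl) {
    Weights w;
    for (int l = 1; l <= 5; ++l) {
        Rcpp::NumericVector W = wl["W" + std::to_string(l)];
        Rcpp::IntegerVector d = W.attr("dim"); // 3,3,Cin,Cout
        int Cin = d[2], Cout = d[3];
        fmat Wm(Cout, 9 * Cin);
        for (int co = 0; co < Cout; ++co)
            for (int k = 0; k < 9 * Cin; ++k)
                Wm(co, k) = (float)W[k + 9 * Cin * co];
        Rcpp::NumericVector bb = wl["b" + std::to_string(l)];
        fvec bv(Cout);
        for (int co = 0; co < Cout; ++co) bv(co) = (float)bb[co];
        w.Wm.push_back(std::move(Wm));
        w.b.push_back(std::move(bv));
        w.cin.push_back(Cin);
        w.cout.push_back(Cout);
    }
    Rcpp::NumericVector W6 = wl["W6"];
    w.w6.set_size(W6.size());
    for (int i = 0; i < (int)W6.size(); ++i) w.w6(i) = (float)W6[i];
    Rcpp::NumericVector b6 = wl["b6"];
    w.b6 = (float)b6[0];
    return w;
}

struct Grads {
    std::vector<fmat> dWm;
    std::vector<fvec> db;
    fvec dw6;
    double db6;
    void init(const Weights& w) {
        dWm.clear(); db.clear();
        for (int l = 0; l < 5; ++l) {
            dWm.push_back(zeros<fmat>(size(w.Wm[l])));
            db.push_back(zeros<fvec>(w.cout[l]));
        }
        dw6 = zeros<fvec>(w.w6.n_elem);
        db6 = 0.0;
    }
};

inline int pooledSize(int s) { return s / 2; }

// im2col for 3x3 same-padding conv on cube a (H x W x C):
// X(o + 9*ci, r + c*H) = a(r + dr, c + dc, ci), o = (dr+1) + 3*(dc+1)
fmat im2col(const fcube& a) {
    const int H = a.n_rows, W = a.n_cols, C = a.n_slices;
    fmat X(9 * C, H * W, fill::zeros);
    for (int ci = 0; ci < C; ++ci) {
        const fmat& sl = a.slice(ci);
        for (int dc = -1; dc <= 1; ++dc)
            for (int dr = -1; dr <= 1; ++dr) {
                const int o = (dr + 1) + 3 * (dc + 1) + 9 * ci;
                for (int c = 0; c < W; ++c) {
                    const int cc = c + dc;
                    if (cc < 0 || cc >= W) continue;
                    const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
                    for (int r = r0; r < r1; ++r)
                        X(o, r + c * H) = sl(r + dr, cc);
                }
            }
    }
    return X;
}

// scatter dX (9C x HW) back into cube gradient (H x W x C)
void col2im(const fmat& dX, fcube& da) {
    const int H = da.n_rows, W = da.n_cols, C = da.n_slices;
    for (int ci = 0; ci < C; ++ci) {
        fmat& sl = da.slice(ci);
        for (int dc = -1; dc <= 1; ++dc)
            for (int dr = -1; dr <= 1; ++dr) {
                const int o = (dr + 1) + 3 * (dc + 1) + 9 * ci;
                for (int c = 0; c < W; ++c) {
                    const int cc = c + dc;
                    if (cc < 0 || cc >= W) continue;
                    const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
                    for (int r = r0; r < r1; ++r)
                        sl(r + dr, cc) += dX(o, r + c * H);
                }
            }
    }
}

// 2x2 max pool with floor semantics; records argmax linear indices
fcube maxpool(const fcube& a, umat& arg) {
    const int H = a.n_rows, W = a.n_cols, C = a.n_slices;
    const int Ho = pooledSize(H), Wo = pooledSize(W);
    fcube out(Ho, Wo, C);
    arg.set_size(Ho * Wo, C);
    for (int ci = 0; ci < C; ++ci) {
        const fmat& sl = a.slice(ci);
        for (int c = 0; c < Wo; ++c)
            for (int r = 0; r < Ho; ++r) {
                int br = 2 * r, bc = 2 * c;
                float v = sl(br, bc); uword am = br + bc * H;
                if (sl(br + 1, bc) > v) { v = sl(br + 1, bc); am = br + 1 + bc * H; }
                if (sl(br, bc + 1) > v) { v = sl(br, bc + 1); am = br + (bc + 1) * H; }
                if (sl(br + 1, bc + 1) > v) { v = sl(br + 1, bc + 1); am = br + 1 + (bc + 1) * H; }
                out(r, c, ci) = v;
                arg(r + c * Ho, ci) = am;
            }
    }
    return out;
}

struct SparseInput {
    std::vector<int> r, c;       // 0-based nonzero pixel coordinates
    std::vector<fvec> f;         // 12-vector of features at each pixel
};

// nonzero pixels = pixels with an active orientation bin (ch 7..12)
SparseInput sparsify(const fcube& x) {
    SparseInput s;
    const int H = x.n_rows, W = x.n_cols;
    for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r) {
            bool nz = false;
            for (int ch = 6; ch < 12; ++ch)
                if (x(r, c, ch) != 0.0f) { nz = true; break; }
            if (nz) {
                fvec f(12);
                for (int ch = 0; ch < 12; ++ch) f(ch) = x(r, c, ch);
                s.r.push_back(r); s.c.push_back(c); s.f.push_back(std::move(f));
            }
        }
    return s;
}

// sparse 3x3 conv for the input layer
fcube conv1Sparse(const SparseInput& s, const Weights& w, int H, int W) {
    const int Cout = w.cout[0];
    fcube z(H, W, Cout);
    for (int co = 0; co < Cout; ++co) z.slice(co).fill(w.b[0](co));
    const fmat& Wm = w.Wm[0]; // (Cout x 9*12), col o + 9*ci
    for (size_t i = 0; i < s.r.size(); ++i) {
        const int r0 = s.r[i], c0 = s.c[i];
        for (int dc = -1; dc <= 1; ++dc) {
            const int tc = c0 - dc;
            if (tc < 0 || tc >= W) continue;
            for (int dr = -1; dr <= 1; ++dr) {
                const int tr = r0 - dr;
                if (tr < 0 || tr >= H) continue;
                const int o = (dr + 1) + 3 * (dc + 1);
                for (int co = 0; co < Cout; ++co) {
                    float acc = 0.0f;
                    for (int ci = 0; ci < 12; ++ci)
                        acc += Wm(co, o + 9 * ci) * s.f[i](ci);
                    z(tr, tc, co) += acc;
                }
            }
        }
    }
    return z;
}

struct Cache {
    std::vector<fcube> z;       // pre-activations z1..z5
    std::vector<fcube> ap;      // pooled activations a1p..a5p
    std::vector<umat> arg;      // pool argmax
    fcube a5d;                  // after dropout
    fmat logit;
};

// forward one image; if drop != nullptr apply the dropout mask to a5p
void forwardOne(const fcube& x, const Weights& w, float slope,
                const fcube* drop, Cache& cc) {
    cc.z.clear(); cc.ap.clear(); cc.arg.clear();
    SparseInput s = sparsify(x);
    fcube z = conv1Sparse(s, w, x.n_rows, x.n_cols);
    for (int l = 0; l < 5; ++l) {
        if (l > 0) {
            const fcube& prev = cc.ap[l - 1];
            fmat X = im2col(prev);
            fmat Z = w.Wm[l] * X;
            Z.each_col() += w.b[l];
            // Z is (Cout x HW); the cube stores (H x W x C) as HW x C
            // column-major blocks, i.e. Z transposed
            z.set_size(prev.n_rows, prev.n_cols, w.cout[l]);
            fmat Zt = Z.t(); // (HW x Cout)
            std::memcpy(z.memptr(), Zt.memptr(), sizeof(float) * Zt.n_elem);
        }
        cc.z.push_back(z);
        fcube a = z;
        for (uword i = 0; i < a.n_elem; ++i)
            if (a(i) < 0.0f) a(i) *= slope;
        umat arg;
        fcube ap = maxpool(a, arg);
        cc.ap.push_back(std::move(ap));
        cc.arg.push_back(std::move(arg));
    }
    cc.a5d = cc.ap[4];
    if (drop) cc.a5d %= *drop;
    const int h5 = cc.a5d.n_rows, w5 = cc.a5d.n_cols, C5 = cc.a5d.n_slices;
    cc.logit.set_size(h5, w5);
    cc.logit.fill(w.b6);
    for (int co = 0; co < C5; ++co)
        cc.logit += w.w6(co) * cc.a5d.slice(co);
}

// backward one image given d(loss)/d(mean logit); accumulates grads
void backwardOne(const fcube& x, const Weights& w, float slope,
                 const fcube* drop, Cache& cc, float dmean, Grads& g) {
    const int h5 = cc.logit.n_rows, w5 = cc.logit.n_cols;
    const float dlog = dmean / (float)(h5 * w5);
    // classifier conv (1x1)
    const int C5 = cc.a5d.n_slices;
    for (int co = 0; co < C5; ++co)
        g.dw6(co) += dlog * accu(cc.a5d.slice(co));
    g.db6 += dmean;
    fcube da(h5, w5, C5);
    for (int co = 0; co < C5; ++co)
        da.slice(co).fill(dlog * w.w6(co));
    if (drop) da %= *drop;
    // layers 5..1
    for (int l = 4; l >= 0; --l) {
        // unpool into pre-activation-shaped gradient
        const fcube& z = cc.z[l];
        fcube dz(z.n_rows, z.n_cols, z.n_slices, fill::zeros);
        const umat& arg = cc.arg[l];
        const int Ho = da.n_rows, Wo = da.n_cols;
        for (int ci = 0; ci < (int)z.n_slices; ++ci) {
            fmat& dsl = dz.slice(ci);
            const fmat& dasl = da.slice(ci);
            for (int c = 0; c < Wo; ++c)
                for (int r = 0; r < Ho; ++r)
                    dsl(arg(r + c * Ho, ci)) += dasl(r, c);
        }
        // leaky ReLU
        for (uword i = 0; i < dz.n_elem; ++i)
            if (z(i) < 0.0f) dz(i) *= slope;
        // conv backward
        if (l > 0) {
            const fcube& prev = cc.ap[l - 1];
            fmat X = im2col(prev);
            // dz as (Cout x HW)
            const int HW = dz.n_rows * dz.n_cols, Cout = dz.n_slices;
            fmat dZt(HW, Cout);
            std::memcpy(dZt.memptr(), dz.memptr(), sizeof(float) * dz.n_elem);
            fmat dZ = dZt.t();
            g.dWm[l] += dZ * X.t();
            g.db[l] += sum(dZ, 1);
            fmat dX = w.Wm[l].t() * dZ;
            da.set_size(prev.n_rows, prev.n_cols, prev.n_slices);
            da.zeros();
            col2im(dX, da);
        } else {
            // sparse input layer: dW1 only
            SparseInput s = sparsify(x);
            const int H = x.n_rows, W = x.n_cols, Cout = dz.n_slices;
            for (int co = 0; co < Cout; ++co)
                g.db[0](co) += accu(dz.slice(co));
            for (size_t i = 0; i < s.r.size(); ++i) {
                const int r0 = s.r[i], c0 = s.c[i];
                for (int dc = -1; dc <= 1; ++dc) {
                    const int tc = c0 - dc;
                    if (tc < 0 || tc >= W) continue;
                    for (int dr = -1; dr <= 1; ++dr) {
                        const int tr = r0 - dr;
                        if (tr < 0 || tr >= H) continue;
                        const int o = (dr + 1) + 3 * (dc + 1);
                        for (int co = 0; co < Cout; ++co) {
                            const float dv = dz(tr, tc, co);
                            if (dv == 0.0f) continue;
                            for (int ci = 0; ci < 12; ++ci)
                                g.dWm[0](co, o + 9 * ci) += dv * s.f[i](ci);
                        }
                    }
                }
            }
        }
    }
}

fcube cubeFromR(const Rcpp::NumericVector& x, int offset, int H, int W, int C) {
    fcube out(H, W, C);
    const double* p = x.begin() + offset;
    for (uword i = 0; i < out.n_elem; ++i) out(i) = (float)p[i];
    return out;
}

Rcpp::List packGrads(const Weights& w, const Grads& g) {
    Rcpp::List out;
    for (int l = 0; l < 5; ++l) {
        const int Cin = w.cin[l], Cout = w.cout[l];
        Rcpp::NumericVector dW(9 * Cin * Cout);
        for (int co = 0; co < Cout; ++co)
            for (int k = 0; k < 9 * Cin; ++k)
                dW[k + 9 * Cin * co] = g.dWm[l](co, k);
        dW.attr("dim") = Rcpp::IntegerVector::create(3, 3, Cin, Cout);
        out["W" + std::to_string(l + 1)] = dW;
        Rcpp::NumericVector db(Cout);
        for (int co = 0; co < Cout; ++co) db[co] = g.db[l](co);
        out["b" + std::to_string(l + 1)] = db;
    }
    Rcpp::NumericVector dw6(g.dw6.n_elem);
    for (uword i = 0; i < g.dw6.n_elem; ++i) dw6[i] = g.dw6(i);
    out["W6"] = dw6;
    out["b6"] = Rcpp::NumericVector::create(g.db6);
    return out;
}

} // namespace

// [[Rcpp::export(name = "cnn_logit_map")]]
Rcpp::NumericMatrix cnn_logit_map(Rcpp::List weights, Rcpp::NumericVector x,
                                  double slope) {
    Rcpp::IntegerVector d = x.attr("dim");
    Weights w = unpackWeights(weights);
    fcube xc = cubeFromR(x, 0, d[0], d[1], d[2]);
    Cache cc;
    forwardOne(xc, w, (float)slope, nullptr, cc);
    Rcpp::NumericMatrix out(cc.logit.n_rows, cc.logit.n_cols);
    for (uword c = 0; c < cc.logit.n_cols; ++c)
        for (uword r = 0; r < cc.logit.n_rows; ++r)
            out(r, c) = cc.logit(r, c);
    return out;
}

// [[Rcpp::export(name = "cnn_forward_batch")]]
Rcpp::NumericVector cnn_forward_batch(Rcpp::List weights,
                                      Rcpp::NumericVector x, double slope) {
    Rcpp::IntegerVector d = x.attr("dim"); // H, W, 12, N
    const int H = d[0], W = d[1], C = d[2], N = d[3];
    Weights w = unpackWeights(weights);
    Rcpp::NumericVector out(N);
    Cache cc;
    for (int i = 0; i < N; ++i) {
        fcube xc = cubeFromR(x, (long)H * W * C * i, H, W, C);
        forwardOne(xc, w, (float)slope, nullptr, cc);
        out[i] = mean(mean(cc.logit));
    }
    return out;
}

// One training step on a batch: forward, batch-norm of the scalar mean
// logits, binary cross-entropy, full backward. Returns the loss, the
// gradients (same shapes as the weights, plus gamma/beta), the batch
// statistics and the per-image mean logits.
// [[Rcpp::export(name = "cnn_train_step")]]
Rcpp::List cnn_train_step(Rcpp::List weights, Rcpp::NumericVector x,
                          Rcpp::NumericVector y, double gamma, double beta,
                          double eps, double slope,
                          Rcpp::NumericVector dropmask) {
    Rcpp::IntegerVector d = x.attr("dim"); // H, W, 12, N
    const int H = d[0], W = d[1], C = d[2], N = d[3];
    Weights w = unpackWeights(weights);
    const bool useDrop = dropmask.size() > 0;
    int h5 = 0, w5 = 0;
    if (useDrop) {
        Rcpp::IntegerVector dd = dropmask.attr("dim");
        h5 = dd[0]; w5 = dd[1];
    }
    // pass 1: mean logits
    vec m(N);
    {
        Cache cc;
        for (int i = 0; i < N; ++i) {
            fcube xc = cubeFromR(x, (long)H * W * C * i, H, W, C);
            fcube dm;
            const fcube* dp = nullptr;
            if (useDrop) {
                dm = cubeFromR(dropmask, (long)h5 * w5 * w.cout[4] * i,
                               h5, w5, w.cout[4]);
                dp = &dm;
            }
            forwardOne(xc, w, (float)slope, dp, cc);
            m(i) = mean(mean(cc.logit));
        }
    }
    // batch norm (population variance) + sigmoid + BCE
    const double mu = mean(m);
    const double v = mean(square(m - mu));
    const double sd = std::sqrt(v + eps);
    vec xhat = (m - mu) / sd;
    vec z = gamma * xhat + beta;
    vec p = 1.0 / (1.0 + exp(-z));
    double loss = 0.0;
    for (int i = 0; i < N; ++i) {
        const double pi = std::min(std::max(p(i), 1e-12), 1.0 - 1e-12);
        loss += -(y[i] * std::log(pi) + (1.0 - y[i]) * std::log(1.0 - pi));
    }
    loss /= N;
    vec dzv(N);
    for (int i = 0; i < N; ++i) dzv(i) = (p(i) - y[i]) / N;
    const double dgamma = dot(dzv, xhat);
    const double dbeta = accu(dzv);
    vec dxhat = gamma * dzv;
    const double mdx = mean(dxhat);
    const double mdxx = mean(dxhat % xhat);
    vec dm = (dxhat - mdx - xhat * mdxx) / sd;
    // pass 2: forward with cache + backward
    Grads g; g.init(w);
    Cache cc;
    for (int i = 0; i < N; ++i) {
        fcube xc = cubeFromR(x, (long)H * W * C * i, H, W, C);
        fcube dmc;
        const fcube* dp = nullptr;
        if (useDrop) {
            dmc = cubeFromR(dropmask, (long)h5 * w5 * w.cout[4] * i,
                            h5, w5, w.cout[4]);
            dp = &dmc;
        }
        forwardOne(xc, w, (float)slope, dp, cc);
        backwardOne(xc, w, (float)slope, dp, cc, (float)dm(i), g);
    }
    Rcpp::List grads = packGrads(w, g);
    grads["gamma"] = Rcpp::NumericVector::create(dgamma);
    grads["beta"] = Rcpp::NumericVector::create(dbeta);
    return Rcpp::List::create(
        Rcpp::Named("loss") = loss,
        Rcpp::Named("grads") = grads,
        Rcpp::Named("batch_mean") = mu,
        Rcpp::Named("batch_var") = v,
        Rcpp::Named("mean_logits") = Rcpp::NumericVector(m.begin(), m.end()));
}

// Bicubic interpolation (Keys kernel, a = -0.5) with replicated edges.
// [[Rcpp::export(name = "bicubic_resize")]]
Rcpp::NumericMatrix bicubic_resize(Rcpp::NumericMatrix img, int outH,
                                   int outW) {
    const int H = img.nrow(), W = img.ncol();
    Rcpp::NumericMatrix out(outH, outW);
    const double sy = (double)H / outH, sx = (double)W / outW;
    auto kern = [](double t) {
        t = std::fabs(t);
        const double a = -0.5;
        if (t <= 1.0) return (a + 2.0) * t * t * t - (a + 3.0) * t * t + 1.0;
        if (t < 2.0) return a * t * t * t - 5.0 * a * t * t + 8.0 * a * t - 4.0 * a;
        return 0.0;
    };
    auto clampi = [](int v, int lo, int hi) {
        return v < lo ? lo : (v > hi ? hi : v);
    };
    for (int oc = 0; oc < outW; ++oc) {
        const double xin = (oc + 0.5) * sx - 0.5;
        const int x0 = (int)std::floor(xin);
        double wx[4];
        for (int k = 0; k < 4; ++k) wx[k] = kern(xin - (x0 - 1 + k));
        for (int orr = 0; orr < outH; ++orr) {
            const double yin = (orr + 0.5) * sy - 0.5;
            const int y0 = (int)std::floor(yin);
            double wy[4];
            for (int k = 0; k < 4; ++k) wy[k] = kern(yin - (y0 - 1 + k));
            double acc = 0.0, wsum = 0.0;
            for (int kx = 0; kx < 4; ++kx) {
                const int cc = clampi(x0 - 1 + kx, 0, W - 1);
                for (int ky = 0; ky < 4; ++ky) {
                    const int rr = clampi(y0 - 1 + ky, 0, H - 1);
                    const double wgt = wx[kx] * wy[ky];
                    acc += wgt * img(rr, cc);
                    wsum += wgt;
                }
            }
            out(orr, oc) = acc / wsum;
        }
    }
    return out;
}
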
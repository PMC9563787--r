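#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Diploid Li-Stephens forward-backward over ordered pairs of template
// haplotypes. Transitions factorize per haplotype: stay with probability
// (1 - theta), else switch to a uniformly chosen template (including the
// current one), so a one-step update costs O(H^2) via row/column sums.
// Memory is kept at O(sqrt(J) * H^2) by checkpointing the forward table and
// recomputing it segment-wise during the backward sweep.
//
// Implementation notes: alleles are carried as doubles so the emission
// weight of a pair (k, l) at a marker, u[a_k + a_l], becomes the branchless
// ua_k + ad[l] * du_k (du_k = u[a_k + 1] - u[a_k]), keeping every inner loop
// vectorizable. Per-marker rescaling is folded into the scalar emission
// weights of the next step instead of an extra pass over the H^2 table; the
// per-marker posterior normalization makes absolute scales irrelevant.

struct LsWork {
  int H;
  std::vector<double> rs, cs;
};

// out(k,l) = (stay2 * in(k,l) + mix * rs_k + mix * cs_l + jump2 * tot) *
//            (ua_k + ad_l * du_k), returning the total of out
static double transition_emit(const std::vector<double>& in,
                              std::vector<double>& out, LsWork& w,
                              double theta, const double* ad,
                              const double* u) {
  const int H = w.H;
  const double stay2 = (1.0 - theta) * (1.0 - theta);
  const double mix = (1.0 - theta) * theta / H;
  const double jump2 = (theta / H) * (theta / H);
  double tot = 0.0;
  std::fill(w.cs.begin(), w.cs.end(), 0.0);
  for (int k = 0; k < H; ++k) {
    const double* row = in.data() + (size_t)k * H;
    double* csd = w.cs.data();
    double s = 0.0;
    for (int l = 0; l < H; ++l) {
      s += row[l];
      csd[l] += row[l];
    }
    w.rs[k] = s;
    tot += s;
  }
  double newtot = 0.0;
  for (int k = 0; k < H; ++k) {
    double* orow = out.data() + (size_t)k * H;
    const double* irow = in.data() + (size_t)k * H;
    const int ak = (int)ad[k];
    const double ua = u[ak], du = u[ak + 1] - u[ak];
    const double base = jump2 * tot + mix * w.rs[k];
    const double* csd = w.cs.data();
    double s = 0.0;
    for (int l = 0; l < H; ++l) {
      const double v = (stay2 * irow[l] + base + mix * csd[l]) * (ua + ad[l] * du);
      orow[l] = v;
      s += v;
    }
    newtot += s;
  }
  if (newtot <= 0.0) stop("numerical underflow: all-zero emission at a marker");
  return newtot;
}

// g = b .* u (elementwise pair emission), accumulating rs/cs/tot of g
static void premultiply(const std::vector<double>& b, std::vector<double>& g,
                        LsWork& w, const double* ad, const double* u,
                        double& tot) {
  const int H = w.H;
  tot = 0.0;
  std::fill(w.cs.begin(), w.cs.end(), 0.0);
  for (int k = 0; k < H; ++k) {
    const double* brow = b.data() + (size_t)k * H;
    double* grow = g.data() + (size_t)k * H;
    double* csd = w.cs.data();
    const int ak = (int)ad[k];
    const double ua = u[ak], du = u[ak + 1] - u[ak];
    double s = 0.0;
    for (int l = 0; l < H; ++l) {
      const double v = brow[l] * (ua + ad[l] * du);
      grow[l] = v;
      s += v;
      csd[l] += v;
    }
    w.rs[k] = s;
    tot += s;
  }
}

// out(k,l) = stay2 * g(k,l) + mix * rs_k + mix * cs_l + jump2 * tot
static double transition_only(const std::vector<double>& g,
                              std::vector<double>& out, LsWork& w,
                              double theta, double tot) {
  const int H = w.H;
  const double stay2 = (1.0 - theta) * (1.0 - theta);
  const double mix = (1.0 - theta) * theta / H;
  const double jump2 = (theta / H) * (theta / H);
  double newtot = 0.0;
  for (int k = 0; k < H; ++k) {
    const double* grow = g.data() + (size_t)k * H;
    double* orow = out.data() + (size_t)k * H;
    const double base = jump2 * tot + mix * w.rs[k];
    const double* csd = w.cs.data();
    double s = 0.0;
    for (int l = 0; l < H; ++l) {
      const double v = stay2 * grow[l] + base + mix * csd[l];
      orow[l] = v;
      s += v;
    }
    newtot += s;
  }
  if (newtot <= 0.0) stop("numerical underflow in backward recursion");
  return newtot;
}

// [[Rcpp::export(name = ".ls_forward_backward")]]
NumericMatrix ls_forward_backward(IntegerMatrix haps, NumericMatrix lik,
                                  NumericVector theta, double eps,
                                  double min_prob) {
  const int H = haps.nrow();
  const int J = haps.ncol();
  if (lik.nrow() != J || lik.ncol() != 3)
    stop("likelihood matrix must be J x 3");
  if (theta.size() != std::max(J - 1, 0))
    stop("theta must have length J - 1");
  if (H < 1 || J < 1) stop("panel and marker set must be non-empty");

  // P(observed genotype g | template pair genotype g'), allele-wise error eps
  double Pe[3][3];
  const double e = eps, ne = 1.0 - eps;
  Pe[0][0] = ne * ne;  Pe[0][1] = 2 * e * ne;      Pe[0][2] = e * e;
  Pe[1][0] = e * ne;   Pe[1][1] = ne * ne + e * e; Pe[1][2] = e * ne;
  Pe[2][0] = e * e;    Pe[2][1] = 2 * e * ne;      Pe[2][2] = ne * ne;

  // per-marker emission weight by pair genotype:
  // u[j][g'] = sum_g lik(j, g) * Pe[g'][g]
  std::vector<double> U((size_t)J * 3);
  for (int j = 0; j < J; ++j) {
    for (int gp = 0; gp < 3; ++gp) {
      double s = 0.0;
      for (int g = 0; g < 3; ++g) s += lik(j, g) * Pe[gp][g];
      U[(size_t)j * 3 + gp] = std::max(s, min_prob);
    }
  }

  // alleles per marker as doubles (column-major by marker)
  std::vector<double> A((size_t)J * H);
  for (int j = 0; j < J; ++j)
    for (int k = 0; k < H; ++k) A[(size_t)j * H + k] = (double)haps(k, j);

  const size_t S = (size_t)H * H;
  const int K = (int)std::ceil(std::sqrt((double)J));
  const int n_seg = (J + K - 1) / K;

  LsWork w;
  w.H = H;
  w.rs.assign(H, 0.0);
  w.cs.assign(H, 0.0);

  // forward pass, checkpointing the (unnormalized) table at each segment head;
  // the running 1/total is folded into the next marker's emission scalars
  std::vector<std::vector<double>> checkpoint(n_seg);
  std::vector<double> f(S), tmp(S);
  std::vector<double> fmul(J, 1.0);   // scale folded into marker j's emission
  {
    const double* ad = A.data();
    const double* u = U.data();
    double tot = 0.0;
    for (int k = 0; k < H; ++k) {
      double* row = f.data() + (size_t)k * H;
      const int ak = (int)ad[k];
      const double ua = u[ak], du = u[ak + 1] - u[ak];
      double s = 0.0;
      for (int l = 0; l < H; ++l) {
        row[l] = ua + ad[l] * du;
        s += row[l];
      }
      tot += s;
    }
    if (tot <= 0.0) stop("numerical underflow: all-zero emission at a marker");
    checkpoint[0] = f;
    double carry = 1.0 / tot;
    for (int j = 1; j < J; ++j) {
      double uj[3];
      for (int gp = 0; gp < 3; ++gp) uj[gp] = U[(size_t)j * 3 + gp] * carry;
      fmul[j] = carry;
      double t = transition_emit(f, tmp, w, theta[j - 1],
                                 A.data() + (size_t)j * H, uj);
      f.swap(tmp);
      if (j % K == 0) checkpoint[j / K] = f;
      carry = 1.0 / t;
    }
  }

  NumericMatrix post(J, 3);
  std::vector<double> b(S, 1.0), g(S);
  std::vector<std::vector<double>> seg_f((size_t)K);

  for (int s = n_seg - 1; s >= 0; --s) {
    const int j0 = s * K;
    const int j1 = std::min(J - 1, j0 + K - 1);
    // recompute forward inside the segment from its checkpoint
    f = checkpoint[s];
    seg_f[0] = f;
    for (int j = j0 + 1; j <= j1; ++j) {
      double uj[3];
      for (int gp = 0; gp < 3; ++gp) uj[gp] = U[(size_t)j * 3 + gp] * fmul[j];
      transition_emit(f, tmp, w, theta[j - 1], A.data() + (size_t)j * H, uj);
      f.swap(tmp);
      seg_f[j - j0] = f;
    }
    for (int j = j1; j >= j0; --j) {
      const std::vector<double>& fj = seg_f[j - j0];
      const double* ad = A.data() + (size_t)j * H;
      // pair-genotype aggregates of f_j .* b_j via the allele split
      double agg[3] = {0.0, 0.0, 0.0};
      for (int k = 0; k < H; ++k) {
        const double* frow = fj.data() + (size_t)k * H;
        const double* brow = b.data() + (size_t)k * H;
        double s_all = 0.0, s_alt = 0.0;
        for (int l = 0; l < H; ++l) {
          const double fb = frow[l] * brow[l];
          s_all += fb;
          s_alt += fb * ad[l];
        }
        const int ak = (int)ad[k];
        agg[ak] += s_all - s_alt;
        agg[ak + 1] += s_alt;
      }
      // f_j carries the marker-j emission u[g']; divide it out so the
      // genotype split applies lik * Pe exactly once
      const double* uj = U.data() + (size_t)j * 3;
      for (int gp = 0; gp < 3; ++gp) agg[gp] /= uj[gp];
      double pg[3], ptot = 0.0;
      for (int gg = 0; gg < 3; ++gg) {
        double sum = 0.0;
        for (int gp = 0; gp < 3; ++gp) sum += agg[gp] * Pe[gp][gg];
        pg[gg] = lik(j, gg) * sum;
        ptot += pg[gg];
      }
      if (ptot <= 0.0) stop("numerical underflow in posterior at a marker");
      for (int gg = 0; gg < 3; ++gg) post(j, gg) = pg[gg] / ptot;
      // extend backward to marker j - 1: b_{j-1} = T (u_j .* b_j)
      if (j > 0) {
        double btot = 0.0;
        premultiply(b, g, w, ad, uj, btot);
        double t = transition_only(g, b, w, theta[j - 1], btot);
        // rescale lazily: fold 1/t into b via the next premultiply's scalars
        // (cheap explicit scale here keeps the posterior products bounded)
        const double inv = 1.0 / t;
        for (size_t i = 0; i < S; ++i) b[i] *= inv;
      }
    }
  }
  return post;
}
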
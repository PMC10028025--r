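#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Windowed grey-level co-occurrence statistic maps.
//
// For every pixel, a single symmetric co-occurrence matrix is accumulated
// over all pixel pairs at distance 1 in the four standard directions
// (0, 45, 90, 135 degrees) whose both endpoints lie inside the window
// centred on that pixel (windows are clipped at the image border).  Thirteen
// classical second-order statistics are then computed from the normalised
// matrix.  Levels in `q` are 0-based (0..levels-1); statistics that depend
// on the level index use 1-based values, matching the usual tabulations.
//
// Entropies use natural logarithms.  Because every probability is an integer
// count divided by the window pair total, logs are taken from a precomputed
// table of log(k), which keeps the per-pixel cost low.
//
// Returned maps (in order):
//   energy, contrast, correlation, variance, inverse_difference_moment,
//   sum_average, sum_variance, sum_entropy, entropy, difference_variance,
//   difference_entropy, info_measure_1, info_measure_2

static const int N_STATS = 13;

// [[Rcpp::export]]
List glcm_stat_maps_cpp(IntegerMatrix q, int levels, int window) {
  const int nr = q.nrow(), nc = q.ncol();
  if (window < 3 || window % 2 == 0)
    stop("window must be odd and >= 3");
  if (window > nr || window > nc)
    stop("window exceeds image dimensions");
  const int h = window / 2;

  // scratch: joint counts + touched lists
  std::vector<int> joint((size_t)levels * levels, 0);
  std::vector<int> touched;            touched.reserve(512);
  std::vector<int> cx(levels, 0), cy(levels, 0);
  std::vector<int> tx, ty;             tx.reserve(64); ty.reserve(64);
  std::vector<int> csum(2 * levels + 1, 0), cdiff(levels, 0);
  std::vector<int> tsum, tdiff;        tsum.reserve(128); tdiff.reserve(64);

  // log table: max total pairs = 8 * window^2 (generous bound)
  const int maxcnt = 8 * window * window + 2;
  std::vector<double> lntab(maxcnt);
  lntab[0] = 0.0;  // unused
  for (int k = 1; k < maxcnt; ++k) lntab[k] = std::log((double)k);

  List out(N_STATS);
  std::vector<NumericMatrix> maps;
  for (int s = 0; s < N_STATS; ++s) {
    NumericMatrix m(nr, nc);
    maps.push_back(m);
    out[s] = m;
  }

  const int drs[4] = {0, 1, 1, 1};
  const int dcs[4] = {1, 1, 0, -1};

  for (int r = 0; r < nr; ++r) {
    const int r0 = std::max(0, r - h), r1 = std::min(nr - 1, r + h);
    for (int c = 0; c < nc; ++c) {
      const int c0 = std::max(0, c - h), c1 = std::min(nc - 1, c + h);

      int total = 0;
      const int* qp = q.begin();
      for (int d = 0; d < 4; ++d) {
        const int dr = drs[d], dc = dcs[d];
        const int jlo = std::max(c0, c0 - dc), jhi = std::min(c1, c1 - dc);
        const int ilo = std::max(r0, r0 - dr), ihi = std::min(r1, r1 - dr);
        for (int j = jlo; j <= jhi; ++j) {
          const int* col1 = qp + (size_t)j * nr;
          const int* col2 = qp + (size_t)(j + dc) * nr + dr;
          for (int i = ilo; i <= ihi; ++i) {
            const int a = col1[i], b = col2[i];
            int k1 = a * levels + b, k2 = b * levels + a;
            if (joint[k1] == 0) touched.push_back(k1);
            joint[k1]++;
            if (joint[k2] == 0) touched.push_back(k2);
            joint[k2]++;
            total += 2;
          }
        }
      }

      if (total == 0) {  // cannot happen for window >= 3, kept as guard
        for (int s = 0; s < N_STATS; ++s) maps[s](r, c) = NA_REAL;
        continue;
      }
      const double lt = lntab[total];
      const double inv = 1.0 / (double)total;

      // pass 1: marginals, sum and difference distributions
      for (size_t t = 0; t < touched.size(); ++t) {
        const int k = touched[t], cnt = joint[k];
        const int ia = k / levels, ib = k % levels;
        if (cx[ia] == 0) tx.push_back(ia);
        cx[ia] += cnt;
        if (cy[ib] == 0) ty.push_back(ib);
        cy[ib] += cnt;
        const int ks = ia + ib;  // 0-based sum index
        if (csum[ks] == 0) tsum.push_back(ks);
        csum[ks] += cnt;
        const int kd = ia >= ib ? ia - ib : ib - ia;
        if (cdiff[kd] == 0) tdiff.push_back(kd);
        cdiff[kd] += cnt;
      }

      // marginal moments/entropies (1-based level values)
      double mux = 0, muy = 0, sqx = 0, sqy = 0, hx = 0, hy = 0;
      for (size_t t = 0; t < tx.size(); ++t) {
        const int i = tx[t], cnt = cx[i];
        const double p = cnt * inv, v = i + 1.0;
        mux += v * p; sqx += v * v * p;
        hx  -= p * (lntab[cnt] - lt);
      }
      for (size_t t = 0; t < ty.size(); ++t) {
        const int i = ty[t], cnt = cy[i];
        const double p = cnt * inv, v = i + 1.0;
        muy += v * p; sqy += v * v * p;
        hy  -= p * (lntab[cnt] - lt);
      }
      const double varx = sqx - mux * mux, vary = sqy - muy * muy;

      // joint statistics
      double energy = 0, contrast = 0, idm = 0, ent = 0, sxy = 0, hxy1 = 0;
      for (size_t t = 0; t < touched.size(); ++t) {
        const int k = touched[t], cnt = joint[k];
        const int ia = k / levels, ib = k % levels;
        const double p = cnt * inv;
        const int di = ia - ib;
        energy   += p * p;
        contrast += (double)(di * di) * p;
        idm      += p / (1.0 + di * di);
        ent      -= p * (lntab[cnt] - lt);
        sxy      += (ia + 1.0) * (ib + 1.0) * p;
        hxy1     -= p * (lntab[cx[ia]] + lntab[cy[ib]] - 2.0 * lt);
      }

      // sum / difference distributions (sum index shifted back to 1-based:
      // value = ks + 2)
      double sa = 0, se = 0, sq2 = 0;
      for (size_t t = 0; t < tsum.size(); ++t) {
        const int k = tsum[t], cnt = csum[k];
        const double p = cnt * inv, v = k + 2.0;
        sa += v * p; sq2 += v * v * p;
        se -= p * (lntab[cnt] - lt);
      }
      const double sv = sq2 - sa * sa;
      double da = 0, de = 0, dq2 = 0;
      for (size_t t = 0; t < tdiff.size(); ++t) {
        const int k = tdiff[t], cnt = cdiff[k];
        const double p = cnt * inv, v = (double)k;
        da += v * p; dq2 += v * v * p;
        de -= p * (lntab[cnt] - lt);
      }
      const double dv = dq2 - da * da;

      const double sdx = varx > 0 ? std::sqrt(varx) : 0.0;
      const double sdy = vary > 0 ? std::sqrt(vary) : 0.0;
      const double corr = (sdx > 0 && sdy > 0) ? (sxy - mux * muy) / (sdx * sdy) : 0.0;
      const double hxy2 = hx + hy;
      const double hmax = std::max(hx, hy);
      const double imc1 = hmax > 0 ? (ent - hxy1) / hmax : 0.0;
      double imc2arg = 1.0 - std::exp(-2.0 * (hxy2 - ent));
      if (imc2arg < 0) imc2arg = 0;
      const double imc2 = std::sqrt(imc2arg);

      maps[0](r, c)  = energy;
      maps[1](r, c)  = contrast;
      maps[2](r, c)  = corr;
      maps[3](r, c)  = varx;
      maps[4](r, c)  = idm;
      maps[5](r, c)  = sa;
      maps[6](r, c)  = sv;
      maps[7](r, c)  = se;
      maps[8](r, c)  = ent;
      maps[9](r, c)  = dv;
      maps[10](r, c) = de;
      maps[11](r, c) = imc1;
      maps[12](r, c) = imc2;

      // reset scratch
      for (size_t t = 0; t < touched.size(); ++t) joint[touched[t]] = 0;
      touched.clear();
      for (size_t t = 0; t < tx.size(); ++t) cx[tx[t]] = 0;
      tx.clear();
      for (size_t t = 0; t < ty.size(); ++t) cy[ty[t]] = 0;
      ty.clear();
      for (size_t t = 0; t < tsum.size(); ++t) csum[tsum[t]] = 0;
      tsum.clear();
      for (size_t t = 0; t < tdiff.size(); ++t) cdiff[tdiff[t]] = 0;
      tdiff.clear();
    }
  }
  return out;
}

static inline int reflect_idx(int i, int n) {
  // symmetric (edge-duplicating) reflection, robust to multiple folds
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// 2-D cross-correlation with symmetric (reflect) border handling.
// The kernel is applied as-is (no flip); kernel dimensions must be odd.
// Interior pixels (where the kernel fits entirely) take a direct
// pointer-arithmetic path; border bands use a reflected index lookup.
// [[Rcpp::export]]
NumericMatrix conv2_reflect_cpp(NumericMatrix img, NumericMatrix kernel) {
  const int nr = img.nrow(), nc = img.ncol();
  const int kr = kernel.nrow(), kc = kernel.ncol();
  if (kr % 2 == 0 || kc % 2 == 0) stop("kernel dimensions must be odd");
  const int hr = kr / 2, hc = kc / 2;
  NumericMatrix out(nr, nc);
  const double* ip = img.begin();
  const double* kp = kernel.begin();
  double* op = out.begin();

  // interior
  for (int c = hc; c < nc - hc; ++c) {
    for (int r = hr; r < nr - hr; ++r) {
      double acc = 0;
      const double* kcol = kp;
      for (int b = 0; b < kc; ++b) {
        const double* icol = ip + (size_t)(c - hc + b) * nr + (r - hr);
        for (int a = 0; a < kr; ++a) acc += kcol[a] * icol[a];
        kcol += kr;
      }
      op[(size_t)c * nr + r] = acc;
    }
  }

  // border bands via reflected index lookup
  std::vector<int> ridx((size_t)(nr + 2 * hr));
  for (int i = 0; i < nr + 2 * hr; ++i) ridx[i] = reflect_idx(i - hr, nr);
  std::vector<int> cidx((size_t)(nc + 2 * hc));
  for (int j = 0; j < nc + 2 * hc; ++j) cidx[j] = reflect_idx(j - hc, nc);

  for (int c = 0; c < nc; ++c) {
    const bool c_border = (c < hc) || (c >= nc - hc);
    for (int r = 0; r < nr; ++r) {
      if (!c_border && r >= hr && r < nr - hr) { r = nr - hr - 1; continue; }
      double acc = 0;
      for (int b = 0; b < kc; ++b) {
        const double* icol = ip + (size_t)cidx[c + b] * nr;
        const double* kcol = kp + (size_t)b * kr;
        for (int a = 0; a < kr; ++a) acc += kcol[a] * icol[ridx[r + a]];
      }
      op[(size_t)c * nr + r] = acc;
    }
  }
  return out;
}
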
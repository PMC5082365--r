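#include <Rcpp.h>
using namespace Rcpp;

// Compiled kernels for the two inner loops that dominate runtime: the
// PatchMatch approximate nearest-neighbour search over the template library,
// and exhaustive block matching for the affine registration.  Both draw all
// randomness from R's RNG so results are reproducible under set.seed().

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Sum of squared differences between z-normalised patches centred at
// (ai,aj) / (bi,bj); border reads are replicate-clamped, matching the
// patch mean/sd maps computed on the R side.  Early-exits once `bestd`
// is exceeded.
static double znssd(const double *A, int nxa, int nya, double ma, double sa,
                    int ai, int aj,
                    const double *B, int nxb, int nyb, double mb, double sb,
                    int bi, int bj, int half, double bestd) {
  const bool ca = sa > 1e-12, cb = sb > 1e-12;
  double d = 0.0;
  for (int u = -half; u <= half; ++u) {
    const int ia = clampi(ai + u, 0, nxa - 1);
    const int ib = clampi(bi + u, 0, nxb - 1);
    for (int v = -half; v <= half; ++v) {
      const int ja = clampi(aj + v, 0, nya - 1);
      const int jb = clampi(bj + v, 0, nyb - 1);
      const double x = ca ? (A[ia + ja * nxa] - ma) / sa : 0.0;
      const double y = cb ? (B[ib + jb * nxb] - mb) / sb : 0.0;
      const double e = x - y;
      d += e * e;
    }
    if (d > bestd) return d;
  }
  return d;
}

// Insert candidate into the pixel's k-best list (ascending by distance,
// ties broken by lexicographic (template, i, j)); duplicates are dropped.
static void kinsert(int k, int *T, int *I, int *J, double *D,
                    int t, int i, int j, double d) {
  for (int s = 0; s < k; ++s)
    if (T[s] == t && I[s] == i && J[s] == j) return;
  int pos = k;
  for (int s = 0; s < k; ++s) {
    const double ds = D[s];
    if (d < ds || (d == ds && (t < T[s] || (t == T[s] &&
        (i < I[s] || (i == I[s] && j < J[s])))))) { pos = s; break; }
  }
  if (pos >= k) return;
  for (int s = k - 1; s > pos; --s) {
    T[s] = T[s - 1]; I[s] = I[s - 1]; J[s] = J[s - 1]; D[s] = D[s - 1];
  }
  T[pos] = t; I[pos] = i; J[pos] = j; D[pos] = d;
}

// [[Rcpp::export]]
List pm_search(NumericMatrix target, NumericMatrix tmean, NumericMatrix tsd,
               List tmpls, List mmeans, List msds,
               int half, int k, int iters, double decay) {
  const int nx = target.nrow(), ny = target.ncol(), npix = nx * ny;
  const int ntm = tmpls.size();
  std::vector<const double *> TP(ntm), MM(ntm), MS(ntm);
  std::vector<int> MX(ntm), MY(ntm);
  for (int m = 0; m < ntm; ++m) {
    NumericMatrix t = tmpls[m], mm = mmeans[m], ms = msds[m];
    TP[m] = t.begin(); MM[m] = mm.begin(); MS[m] = ms.begin();
    MX[m] = t.nrow(); MY[m] = t.ncol();
  }
  const double *A = target.begin();
  const double *TM = tmean.begin(), *TS = tsd.begin();

  IntegerMatrix outT(k, npix), outI(k, npix), outJ(k, npix);
  NumericMatrix outD(k, npix), trace(npix, iters);
  std::fill(outD.begin(), outD.end(), R_PosInf);
  std::fill(outT.begin(), outT.end(), -1);

  RNGScope scope;

  // random initialisation of every slot
  for (int p = 0; p < npix; ++p) {
    const int i = p % nx, j = p / nx;
    int *T = &outT(0, p); int *I = &outI(0, p); int *J = &outJ(0, p);
    double *D = &outD(0, p);
    for (int tries = 0; tries < 4 * k; ++tries) {
      const int t = (int)(unif_rand() * ntm) % ntm;
      const int ci = (int)(unif_rand() * MX[t]) % MX[t];
      const int cj = (int)(unif_rand() * MY[t]) % MY[t];
      const double d = znssd(A, nx, ny, TM[p], TS[p], i, j,
                             TP[t], MX[t], MY[t],
                             MM[t][ci + cj * MX[t]], MS[t][ci + cj * MX[t]],
                             ci, cj, half, D[k - 1]);
      kinsert(k, T, I, J, D, t, ci, cj, d);
      if (D[k - 1] < R_PosInf && tries >= k) break;
    }
    // guarantee full lists even on degenerate images
    for (int s = 0; s < k; ++s)
      if (T[s] < 0) {
        const int t = s % ntm;
        const double d = znssd(A, nx, ny, TM[p], TS[p], i, j,
                               TP[t], MX[t], MY[t], MM[t][0], MS[t][0],
                               0, 0, half, R_PosInf);
        kinsert(k, T, I, J, D, t, 0, 0, d);
      }
  }

  const int rs_slots = k < 3 ? k : 3;
  for (int it = 0; it < iters; ++it) {
    const bool fwd = (it % 2 == 0);
    for (int pp = 0; pp < npix; ++pp) {
      const int p = fwd ? pp : npix - 1 - pp;
      const int i = p % nx, j = p / nx;
      int *T = &outT(0, p); int *I = &outI(0, p); int *J = &outJ(0, p);
      double *D = &outD(0, p);
      // propagation from the two already-visited neighbours
      const int di[2] = { fwd ? -1 : 1, 0 };
      const int dj[2] = { 0, fwd ? -1 : 1 };
      for (int nb = 0; nb < 2; ++nb) {
        const int pi = i + di[nb], pj = j + dj[nb];
        if (pi < 0 || pi >= nx || pj < 0 || pj >= ny) continue;
        const int q = pi + pj * nx;
        for (int s = 0; s < k; ++s) {
          const int t = outT(s, q);
          const int ci = clampi(outI(s, q) - di[nb], 0, MX[t] - 1);
          const int cj = clampi(outJ(s, q) - dj[nb], 0, MY[t] - 1);
          const double d = znssd(A, nx, ny, TM[p], TS[p], i, j,
                                 TP[t], MX[t], MY[t],
                                 MM[t][ci + cj * MX[t]], MS[t][ci + cj * MX[t]],
                                 ci, cj, half, D[k - 1]);
          kinsert(k, T, I, J, D, t, ci, cj, d);
        }
      }
      // random search with exponentially shrinking radii (space and library)
      for (int s = 0; s < rs_slots; ++s) {
        const int t0 = T[s], i0 = I[s], j0 = J[s];
        double r = (double)(MX[t0] > MY[t0] ? MX[t0] : MY[t0]);
        double tr = (double)ntm;
        while (r >= 1.0) {
          const int ci = clampi(i0 + (int)std::floor(unif_rand() * (2 * r + 1)) - (int)r,
                                0, MX[t0] - 1);
          const int cj = clampi(j0 + (int)std::floor(unif_rand() * (2 * r + 1)) - (int)r,
                                0, MY[t0] - 1);
          int ct = t0;
          if (ntm > 1) {
            const int trad = (int)tr;
            ct = clampi(t0 + (int)std::floor(unif_rand() * (2 * trad + 1)) - trad,
                        0, ntm - 1);
          }
          const double d = znssd(A, nx, ny, TM[p], TS[p], i, j,
                                 TP[ct], MX[ct], MY[ct],
                                 MM[ct][ci + cj * MX[ct]], MS[ct][ci + cj * MX[ct]],
                                 ci, cj, half, D[k - 1]);
          kinsert(k, T, I, J, D, ct, ci, cj, d);
          r *= decay;
          tr = tr * decay < 1.0 ? 1.0 : tr * decay;
        }
      }
    }
    for (int p = 0; p < npix; ++p) trace(p, it) = outD(0, p);
  }

  return List::create(_["t"] = outT, _["i"] = outI, _["j"] = outJ,
                      _["d"] = outD, _["trace"] = trace);
}

// Exhaustive NCC block matching.  Blocks are `bsize` x `bsize` squares whose
// top-left target pixel is (si, sj) (0-based); the template is scanned over
// integer offsets within `radius`, and the best offset is refined to
// sub-pixel precision by a 1D parabola fit on the NCC surface.
// [[Rcpp::export]]
List block_match(NumericMatrix target, NumericMatrix tmpl,
                 IntegerVector si, IntegerVector sj,
                 int bsize, int radius, double eps_sd) {
  const int nb = si.size();
  const int nxt = tmpl.nrow(), nyt = tmpl.ncol();
  const int n = bsize * bsize;
  NumericVector du(nb), dv(nb), score(nb);
  LogicalVector valid(nb);
  const int w = 2 * radius + 1;
  std::vector<double> S(w * w);
  std::vector<double> blk(n);

  for (int b = 0; b < nb; ++b) {
    const int bi = si[b], bj = sj[b];
    double sa = 0, sa2 = 0;
    for (int v = 0; v < bsize; ++v)
      for (int u = 0; u < bsize; ++u) {
        const double x = target(bi + u, bj + v);
        blk[u + v * bsize] = x; sa += x; sa2 += x * x;
      }
    const double ma = sa / n;
    const double va = sa2 / n - ma * ma;
    valid[b] = false; du[b] = 0; dv[b] = 0; score[b] = -2.0;
    if (va <= eps_sd * eps_sd) continue;
    std::fill(S.begin(), S.end(), -2.0);
    int bu = 0, bv = 0; double best = -2.0;
    for (int ov = -radius; ov <= radius; ++ov) {
      for (int ou = -radius; ou <= radius; ++ou) {
        const int ti = bi + ou, tj = bj + ov;
        if (ti < 0 || tj < 0 || ti + bsize > nxt || tj + bsize > nyt) continue;
        double sb = 0, sb2 = 0, sab = 0;
        for (int v = 0; v < bsize; ++v)
          for (int u = 0; u < bsize; ++u) {
            const double y = tmpl(ti + u, tj + v);
            sb += y; sb2 += y * y; sab += y * blk[u + v * bsize];
          }
        const double mb = sb / n;
        const double vb = sb2 / n - mb * mb;
        if (vb <= eps_sd * eps_sd) continue;
        const double ncc = (sab / n - ma * mb) / std::sqrt(va * vb);
        S[(ou + radius) + (ov + radius) * w] = ncc;
        if (ncc > best) { best = ncc; bu = ou; bv = ov; }
      }
    }
    if (best <= -2.0) continue;
    double fu = (double)bu, fv = (double)bv;
    // parabola refinement along each axis where neighbours exist
    if (bu > -radius && bu < radius) {
      const double c0 = S[(bu - 1 + radius) + (bv + radius) * w];
      const double c1 = best;
      const double c2 = S[(bu + 1 + radius) + (bv + radius) * w];
      const double den = c0 - 2 * c1 + c2;
      if (c0 > -2 && c2 > -2 && den < -1e-12) {
        double off = 0.5 * (c0 - c2) / den;
        if (off > 0.5) off = 0.5; if (off < -0.5) off = -0.5;
        fu += off;
      }
    }
    if (bv > -radius && bv < radius) {
      const double c0 = S[(bu + radius) + (bv - 1 + radius) * w];
      const double c1 = best;
      const double c2 = S[(bu + radius) + (bv + 1 + radius) * w];
      const double den = c0 - 2 * c1 + c2;
      if (c0 > -2 && c2 > -2 && den < -1e-12) {
        double off = 0.5 * (c0 - c2) / den;
        if (off > 0.5) off = 0.5; if (off < -0.5) off = -0.5;
        fv += off;
      }
    }
    du[b] = fu; dv[b] = fv; score[b] = best; valid[b] = true;
  }
  return List::create(_["du"] = du, _["dv"] = dv, _["ncc"] = score,
                      _["valid"] = valid);
}
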
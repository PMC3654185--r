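#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Multipoint IBD for a nuclear family: HMM over inheritance vectors.
// State encoding: 2 bits per sib; bit (2*i) = paternal meiosis of sib i
// (which of the father's two ordered allele slots was transmitted),
// bit (2*i+1) = maternal meiosis.  Transitions between adjacent map
// positions flip each bit independently with probability theta (Haldane,
// no interference), which is exactly the Markov structure the map
// function guarantees.

// Apply the per-bit transition kernel to a state-probability vector.
static void bit_transition(std::vector<double> &v, int nbits, double theta) {
  if (theta <= 0.0) return;
  const int n = 1 << nbits;
  for (int b = 0; b < nbits; ++b) {
    const int mask = 1 << b;
    for (int i = 0; i < n; ++i) {
      if (i & mask) continue;
      const double a = v[i], c = v[i | mask];
      v[i] = (1.0 - theta) * a + theta * c;
      v[i | mask] = theta * a + (1.0 - theta) * c;
    }
  }
}

static void normalize(std::vector<double> &v) {
  double s = 0.0;
  for (double x : v) s += x;
  if (s > 0.0) for (double &x : v) x /= s;
}

// Emission P(observed genotypes at one marker | inheritance vector).
// Sums over the per-child orientation (which observed allele is paternal)
// and over ordered parental genotypes: the two orderings of an observed
// unordered parental genotype get weight 1/2 each; an ungenotyped parent
// is integrated out slot-by-slot under HWE founder allele frequencies.
static void marker_emission(std::vector<double> &em, int s,
                            const int *sa, const int *sb, // sib alleles, 0=missing
                            int fa1, int fa2, int mo1, int mo2,
                            const NumericVector &freq) {
  const int nstate = 1 << (2 * s);
  std::vector<int> obs; // indices of sibs with observed genotypes
  obs.reserve(s);
  for (int i = 0; i < s; ++i)
    if (sa[i] > 0 && sb[i] > 0) obs.push_back(i);
  const int nobs = (int)obs.size();

  std::vector<int> het(nobs, 0);
  for (int k = 0; k < nobs; ++k) het[k] = (sa[obs[k]] != sb[obs[k]]) ? 1 : 0;

  auto founder_factor = [&](int g1, int g2, int c1, int c2) -> double {
    // genotyped parent with ordered slots summed over the 2 orderings
    if (g1 > 0) {
      double f = 0.0;
      if ((c1 == 0 || c1 == g1) && (c2 == 0 || c2 == g2)) f += 0.5;
      if ((c1 == 0 || c1 == g2) && (c2 == 0 || c2 == g1)) f += 0.5;
      return f;
    }
    // ungenotyped: independent HWE draws per slot
    double f = 1.0;
    if (c1 > 0) f *= freq[c1 - 1];
    if (c2 > 0) f *= freq[c2 - 1];
    return f;
  };

  for (int v = 0; v < nstate; ++v) {
    double total = 0.0;
    const int ncomb = 1 << nobs;
    for (int ori = 0; ori < ncomb; ++ori) {
      bool skip = false;
      // father slot constraints (0 = unconstrained)
      int fc1 = 0, fc2 = 0, mc1 = 0, mc2 = 0;
      for (int k = 0; k < nobs && !skip; ++k) {
        const int i = obs[k];
        if (!het[k] && (ori >> k & 1)) { skip = true; break; } // homozygote: one orientation
        const int pa = (ori >> k & 1) ? sb[i] : sa[i]; // paternal allele
        const int ma = (ori >> k & 1) ? sa[i] : sb[i]; // maternal allele
        const int pslot = (v >> (2 * i)) & 1;
        const int mslot = (v >> (2 * i + 1)) & 1;
        int &fc = pslot ? fc2 : fc1;
        int &mc = mslot ? mc2 : mc1;
        if (fc == 0) fc = pa; else if (fc != pa) { skip = true; break; }
        if (mc == 0) mc = ma; else if (mc != ma) { skip = true; break; }
      }
      if (skip) continue;
      const double ff = founder_factor(fa1, fa2, fc1, fc2);
      if (ff == 0.0) continue;
      const double mf = founder_factor(mo1, mo2, mc1, mc2);
      if (mf == 0.0) continue;
      total += ff * mf;
    }
    em[v] = total;
  }
}

// [[Rcpp::export]]
List hmm_ibd_family(IntegerMatrix sib_gt, IntegerVector fa_gt, IntegerVector mo_gt,
                    List freqs, NumericVector pos, NumericVector grid) {
  const int s = sib_gt.nrow();
  const int m = pos.size();
  if (s < 1) stop("family must contain at least one sib");
  if (s > 8) stop("more than 8 sibs not supported by the inheritance-vector HMM");
  const int nbits = 2 * s;
  const int nstate = 1 << nbits;
  const int ng = grid.size();

  auto theta_of = [](double d) {
    return 0.5 * (1.0 - std::exp(-2.0 * d / 100.0));
  };

  // emissions, with Mendelian-inconsistent markers excluded (all-zero row)
  std::vector<std::vector<double>> em(m, std::vector<double>(nstate, 1.0));
  LogicalVector excluded(m);
  std::vector<int> sa(s), sb(s);
  for (int k = 0; k < m; ++k) {
    for (int i = 0; i < s; ++i) { sa[i] = sib_gt(i, 2 * k); sb[i] = sib_gt(i, 2 * k + 1); }
    NumericVector fr = freqs[k];
    marker_emission(em[k], s, sa.data(), sb.data(),
                    fa_gt[2 * k], fa_gt[2 * k + 1], mo_gt[2 * k], mo_gt[2 * k + 1], fr);
    double tot = 0.0;
    for (double x : em[k]) tot += x;
    if (tot <= 0.0) {
      excluded[k] = true;
      std::fill(em[k].begin(), em[k].end(), 1.0);
    } else {
      for (double &x : em[k]) x /= tot; // scale only; posteriors unaffected
    }
  }

  // forward (alpha_k includes emission at k) and scaled b_k = E_k * beta_k
  std::vector<std::vector<double>> alpha(m), btil(m);
  {
    std::vector<double> cur(nstate, 1.0 / nstate);
    for (int k = 0; k < m; ++k) {
      if (k > 0) bit_transition(cur, nbits, theta_of(pos[k] - pos[k - 1]));
      for (int v = 0; v < nstate; ++v) cur[v] *= em[k][v];
      normalize(cur);
      alpha[k] = cur;
    }
    std::vector<double> bk(nstate, 1.0);
    for (int k = m - 1; k >= 0; --k) {
      if (k < m - 1) {
        std::vector<double> tmp = btil[k + 1];
        bit_transition(tmp, nbits, theta_of(pos[k + 1] - pos[k]));
        bk = tmp;
      } else {
        std::fill(bk.begin(), bk.end(), 1.0);
      }
      btil[k] = bk;
      for (int v = 0; v < nstate; ++v) btil[k][v] *= em[k][v];
      normalize(btil[k]);
    }
  }

  // sib pairs and per-state IBD counts
  const int npair = s * (s - 1) / 2;
  IntegerMatrix pairs(npair > 0 ? npair : 0, 2);
  std::vector<std::vector<int>> ibd_of_state;
  {
    int q = 0;
    for (int i = 0; i < s; ++i)
      for (int j = i + 1; j < s; ++j) {
        pairs(q, 0) = i + 1; pairs(q, 1) = j + 1;
        std::vector<int> row(nstate);
        for (int v = 0; v < nstate; ++v) {
          int c = 0;
          if (((v >> (2 * i)) & 1) == ((v >> (2 * j)) & 1)) ++c;
          if (((v >> (2 * i + 1)) & 1) == ((v >> (2 * j + 1)) & 1)) ++c;
          row[v] = c;
        }
        ibd_of_state.push_back(row);
        ++q;
      }
  }

  NumericMatrix p0(npair, ng), p1(npair, ng), p2(npair, ng);
  std::vector<double> post(nstate);
  for (int g = 0; g < ng; ++g) {
    const double c = grid[g];
    // locate bracketing markers
    int right = 0;
    while (right < m && pos[right] < c - 1e-9) ++right;
    const bool at_marker = (right < m && std::fabs(pos[right] - c) <= 1e-9);
    if (m == 0) {
      std::fill(post.begin(), post.end(), 1.0 / nstate);
    } else if (at_marker) {
      // posterior at marker: alpha_k * beta_k = alpha_k * (btil_k / em_k)
      for (int v = 0; v < nstate; ++v) {
        const double e = em[right][v];
        post[v] = (e > 0.0) ? alpha[right][v] * btil[right][v] / e : 0.0;
      }
    } else {
      std::vector<double> fwd(nstate, 1.0 / nstate), bwd(nstate, 1.0);
      if (right > 0) {
        fwd = alpha[right - 1];
        bit_transition(fwd, nbits, theta_of(c - pos[right - 1]));
      }
      if (right < m) {
        bwd = btil[right];
        bit_transition(bwd, nbits, theta_of(pos[right] - c));
      }
      for (int v = 0; v < nstate; ++v) post[v] = fwd[v] * bwd[v];
    }
    normalize(post);
    for (int q = 0; q < npair; ++q) {
      double pr[3] = {0.0, 0.0, 0.0};
      const std::vector<int> &row = ibd_of_state[q];
      for (int v = 0; v < nstate; ++v) pr[row[v]] += post[v];
      p0(q, g) = pr[0]; p1(q, g) = pr[1]; p2(q, g) = pr[2];
    }
  }

  return List::create(_["pairs"] = pairs, _["p0"] = p0, _["p1"] = p1,
                      _["p2"] = p2, _["excluded"] = excluded);
}
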
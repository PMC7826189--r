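#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap Smith-Waterman (Gotoh three-state recurrence).
// q, t: 0-based residue codes into `smat` (square score matrix).
// gap_open/gap_ext: positive costs; a gap of length k costs open + k*ext
// (BLAST convention). Ties break toward the lexicographically smallest
// (q_start, t_start). Returns score and 0-based half-open coordinates;
// score <= 0 means no positive-scoring local alignment exists.
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector t, NumericMatrix smat,
                  double gap_open, double gap_ext) {
  const int n = q.size(), m = t.size();
  const double gi = gap_open + gap_ext;  // first gapped residue
  const double NEG = -1e30;
  const long NOSTART = (long)(n + 1) * (m + 1) + m + 1;

  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<double> Fprev(m + 1, NEG), Fcur(m + 1, NEG);
  std::vector<double> Ecur(m + 1, NEG);
  std::vector<long> sHprev(m + 1, 0), sHcur(m + 1, 0);
  std::vector<long> sFprev(m + 1, NOSTART), sFcur(m + 1, NOSTART);
  std::vector<long> sEcur(m + 1, NOSTART);

  double best = 0.0;
  long bestStart = NOSTART;
  int bestI = 0, bestJ = 0;

  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0.0; Ecur[0] = NEG; Fcur[0] = NEG;
    sHcur[0] = 0; sEcur[0] = NOSTART; sFcur[0] = NOSTART;
    for (int j = 1; j <= m; ++j) {
      // E: gap in query, consumes target; depends on (i, j-1)
      {
        double vo = Hcur[j - 1] - gi, ve = Ecur[j - 1] - gap_ext;
        if (vo > ve || (vo == ve && sHcur[j - 1] <= sEcur[j - 1])) {
          Ecur[j] = vo; sEcur[j] = sHcur[j - 1];
        } else {
          Ecur[j] = ve; sEcur[j] = sEcur[j - 1];
        }
      }
      // F: gap in target, consumes query; depends on (i-1, j)
      {
        double vo = Hprev[j] - gi, ve = Fprev[j] - gap_ext;
        if (vo > ve || (vo == ve && sHprev[j] <= sFprev[j])) {
          Fcur[j] = vo; sFcur[j] = sHprev[j];
        } else {
          Fcur[j] = ve; sFcur[j] = sFprev[j];
        }
      }
      // H: max(0, diag + s, E, F)
      double diagv = Hprev[j - 1] + smat(q[i - 1], t[j - 1]);
      long diagS = (Hprev[j - 1] > 0.0) ? sHprev[j - 1]
                                        : (long)(i - 1) * (m + 1) + (j - 1);
      double h = diagv; long sh = diagS;
      if (Ecur[j] > h || (Ecur[j] == h && sEcur[j] < sh)) { h = Ecur[j]; sh = sEcur[j]; }
      if (Fcur[j] > h || (Fcur[j] == h && sFcur[j] < sh)) { h = Fcur[j]; sh = sFcur[j]; }
      if (h < 0.0) { h = 0.0; sh = 0; }
      Hcur[j] = h; sHcur[j] = sh;
      if (h > best || (h == best && h > 0.0 && sh < bestStart)) {
        best = h; bestStart = sh; bestI = i; bestJ = j;
      }
    }
    std::swap(Hprev, Hcur); std::swap(sHprev, sHcur);
    std::swap(Fprev, Fcur); std::swap(sFprev, sFcur);
  }

  if (best <= 0.0)
    return List::create(_["score"] = 0.0);
  int sq = (int)(bestStart / (m + 1)), st = (int)(bestStart % (m + 1));
  return List::create(_["score"] = best,
                      _["q_start"] = sq, _["q_end"] = bestI,
                      _["t_start"] = st, _["t_end"] = bestJ);
}

// Viterbi alignment of a profile (glocal: global in the profile, local in
// the sequence) with match/insert/delete states. `emis` is L x A log-odds
// for match emissions; insert states emit at background (log-odds 0).
// `trans`: named-order vector c(mm, mi, im, ii, md, dm, dd) of log2
// transition scores. Returns best score in bits plus 0-based half-open
// coordinates of the emitted region in the sequence.
// [[Rcpp::export]]
List profile_viterbi_cpp(IntegerVector seq, NumericMatrix emis,
                         NumericVector trans) {
  const int n = seq.size(), L = emis.nrow();
  const double t_mm = trans[0], t_mi = trans[1], t_im = trans[2],
               t_ii = trans[3], t_md = trans[4], t_dm = trans[5],
               t_dd = trans[6];
  const double NEG = -1e30;
  const int NOPOS = -1;

  // rows over profile index j; columns i = 0..n residues consumed
  std::vector<double> Mp(n + 1, NEG), Ip(n + 1, NEG), Dp(n + 1, NEG);
  std::vector<double> Mc(n + 1, NEG), Ic(n + 1, NEG), Dc(n + 1, NEG);
  std::vector<int> sMp(n + 1, NOPOS), sIp(n + 1, NOPOS), sDp(n + 1, NOPOS);
  std::vector<int> sMc(n + 1, NOPOS), sIc(n + 1, NOPOS), sDc(n + 1, NOPOS);
  std::vector<int> eMp(n + 1, NOPOS), eIp(n + 1, NOPOS), eDp(n + 1, NOPOS);
  std::vector<int> eMc(n + 1, NOPOS), eIc(n + 1, NOPOS), eDc(n + 1, NOPOS);

  for (int j = 1; j <= L; ++j) {
    std::fill(Mc.begin(), Mc.end(), NEG);
    std::fill(Ic.begin(), Ic.end(), NEG);
    std::fill(Dc.begin(), Dc.end(), NEG);
    for (int i = 0; i <= n; ++i) {
      // M_j emits residue i (requires i >= 1)
      if (i >= 1) {
        if (j == 1) {
          // free entry anywhere in the sequence
          Mc[i] = emis(0, seq[i - 1]);
          sMc[i] = i - 1; eMc[i] = i;
        } else {
          double vm = Mp[i - 1] + t_mm, vi = Ip[i - 1] + t_im,
                 vd = Dp[i - 1] + t_dm;
          double v = vm; int s = sMp[i - 1];
          if (vi > v) { v = vi; s = sIp[i - 1]; }
          if (vd > v) { v = vd; s = sDp[i - 1]; }
          Mc[i] = v + emis(j - 1, seq[i - 1]);
          sMc[i] = s; eMc[i] = i;
          if (sMc[i] == NOPOS) sMc[i] = i - 1;  // first emission on a D-entry path
        }
      }
      // D_j consumes nothing
      if (j == 1) {
        Dc[i] = t_md;  // entry through an initial deletion
        sDc[i] = NOPOS; eDc[i] = NOPOS;
      } else {
        double vm = Mp[i] + t_md, vd = Dp[i] + t_dd;
        if (vm >= vd) { Dc[i] = vm; sDc[i] = sMp[i]; eDc[i] = eMp[i]; }
        else { Dc[i] = vd; sDc[i] = sDp[i]; eDc[i] = eDp[i]; }
      }
      // I_j emits residue i after match j
      if (i >= 1) {
        double vm = Mc[i - 1] + t_mi, vi = Ic[i - 1] + t_ii;
        if (vm >= vi) { Ic[i] = vm; sIc[i] = sMc[i - 1]; }
        else { Ic[i] = vi; sIc[i] = sIc[i - 1]; }
        eIc[i] = i;
      }
    }
    std::swap(Mp, Mc); std::swap(sMp, sMc); std::swap(eMp, eMc);
    std::swap(Ip, Ic); std::swap(sIp, sIc); std::swap(eIp, eIc);
    std::swap(Dp, Dc); std::swap(sDp, sDc); std::swap(eDp, eDc);
  }

  double best = NEG; int bs = NOPOS, be = NOPOS;
  for (int i = 0; i <= n; ++i) {
    if (Mp[i] > best) { best = Mp[i]; bs = sMp[i]; be = eMp[i]; }
    if (Dp[i] > best) { best = Dp[i]; bs = sDp[i]; be = eDp[i]; }
  }
  return List::create(_["score"] = best, _["start"] = bs, _["end"] = be);
}
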
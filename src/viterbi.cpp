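#include <Rcpp.h>
using namespace Rcpp;

// Profile-HMM Viterbi in log2-odds space.
//
// Model layout: positions 0..k, where position 0 is the begin state (an M
// with no emission), positions 1..k are match states, each position j has
// an insert state I_j, and positions 1..k have delete states D_j.  The
// transition table has k+1 rows (positions 0..k); row j holds the nine
// log2 transition scores out of position-j states in the order
// MM MI MD IM II ID DM DI DD, where the "to" state lives at position j+1
// for M/D targets and at position j for I targets.  Row k is only used for
// the terminal insert state.  Exit from any position-k state is free.
//
// lmatch: k x 21 matrix of log2(match emission / background); column 21
//         (index 20) is the 'X'/unknown residue and must be zero.
// target: integer codes 0..19, or 20 for unknown residues.
// global: if true the model must be traversed 1..k and the whole target
//         consumed; if false (local) entry/exit at any match state is free
//         and flanking target residues cost nothing.

static const double NEG = -1e30;

inline double max3(double a, double b, double c, int &arg) {
  double m = a; arg = 0;
  if (b > m) { m = b; arg = 1; }
  if (c > m) { m = c; arg = 2; }
  return m;
}

// [[Rcpp::export(name = ".viterbi_dp")]]
List viterbi_dp(NumericMatrix lmatch, NumericMatrix ltrans,
                IntegerVector target, bool global) {
  const int k = lmatch.nrow();
  const int L = target.size();
  if (k < 1) stop("profile has no match states");
  if (L < 1) stop("empty target");
  if (ltrans.nrow() != k + 1 || ltrans.ncol() != 9)
    stop("transition table must be (k+1) x 9");

  // columns of ltrans
  enum { MM = 0, MI, MD, IM, II, ID, DM, DI, DD };

  NumericMatrix VM(k + 1, L + 1), VI(k + 1, L + 1), VD(k + 1, L + 1);
  // back pointers: 0 = from M, 1 = from I, 2 = from D, 3 = entry/begin
  IntegerMatrix BM(k + 1, L + 1), BI(k + 1, L + 1), BD(k + 1, L + 1);
  std::fill(VM.begin(), VM.end(), NEG);
  std::fill(VI.begin(), VI.end(), NEG);
  std::fill(VD.begin(), VD.end(), NEG);
  std::fill(BM.begin(), BM.end(), -1);
  std::fill(BI.begin(), BI.end(), -1);
  std::fill(BD.begin(), BD.end(), -1);

  if (global) {
    VM(0, 0) = 0.0;  // begin
    for (int i = 1; i <= L; i++) {  // leading inserts through I_0
      int arg;
      double best = max3(VM(0, i - 1) + ltrans(0, MI),
                         VI(0, i - 1) + ltrans(0, II), NEG, arg);
      VI(0, i) = best;  // insert emission log-odds is zero
      BI(0, i) = arg;
    }
  }

  for (int j = 1; j <= k; j++) {
    for (int i = 0; i <= L; i++) {
      int arg;
      // delete: from position j-1, no emission
      double d = max3(VM(j - 1, i) + ltrans(j - 1, MD),
                      VI(j - 1, i) + ltrans(j - 1, ID),
                      VD(j - 1, i) + ltrans(j - 1, DD), arg);
      if (d > NEG / 2) { VD(j, i) = d; BD(j, i) = arg; }
      if (i >= 1) {
        // match: consumes target[i-1]
        double em = lmatch(j - 1, target[i - 1]);
        double best = max3(VM(j - 1, i - 1) + ltrans(j - 1, MM),
                           VI(j - 1, i - 1) + ltrans(j - 1, IM),
                           VD(j - 1, i - 1) + ltrans(j - 1, DM), arg);
        if (!global && 0.0 > best) { best = 0.0; arg = 3; }  // free entry
        if (best > NEG / 2) { VM(j, i) = em + best; BM(j, i) = arg; }
        // insert at position j: consumes target[i-1], emission log-odds 0
        double ins = max3(VM(j, i - 1) + ltrans(j, MI),
                          VI(j, i - 1) + ltrans(j, II),
                          VD(j, i - 1) + ltrans(j, DI), arg);
        if (ins > NEG / 2) { VI(j, i) = ins; BI(j, i) = arg; }
      }
    }
  }

  // terminal insert loop at position k already handled (j == k row above).
  double best = NEG;
  int end_state = -1, end_j = -1, end_i = -1;
  if (global) {
    double cands[3] = { VM(k, L), VI(k, L), VD(k, L) };
    for (int s = 0; s < 3; s++)
      if (cands[s] > best) { best = cands[s]; end_state = s; }
    end_j = k; end_i = L;
  } else {
    for (int j = 1; j <= k; j++)
      for (int i = 1; i <= L; i++)
        if (VM(j, i) > best) { best = VM(j, i); end_state = 0; end_j = j; end_i = i; }
  }
  if (end_state < 0 || best <= NEG / 2)
    stop("no admissible alignment path");

  // traceback to recover matched states and aligned target span
  int matched = 0;
  int first_m = -1, last_m = -1;
  int j = end_j, i = end_i, s = end_state;
  while (true) {
    int prev;
    if (s == 0) {        // match state at (j, i)
      matched++;
      if (last_m < 0) last_m = i;
      first_m = i;
      prev = BM(j, i);
      if (prev == 3) break;            // local entry
      if (j == 1 && prev == 0 && i == 1 && global) { /* from begin */ }
      j--; i--;
    } else if (s == 1) { // insert at (j, i)
      prev = BI(j, i);
      i--;
    } else {             // delete at (j, i)
      prev = BD(j, i);
      j--;
    }
    if (prev < 0) stop("traceback failure");
    s = prev;
    if (global && j == 0 && s == 0) break;   // reached begin
  }

  int ali_from, ali_to;
  if (first_m > 0) { ali_from = first_m; ali_to = last_m; }
  else { ali_from = 1; ali_to = L; }         // degenerate all-insert global path

  return List::create(_["bits"] = best,
                      _["ali_from"] = ali_from,
                      _["ali_to"] = ali_to,
                      _["matched_states"] = matched);
}
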
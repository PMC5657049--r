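#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Local (Smith-Waterman-style entry/exit over match states) Viterbi for a
// Plan7-like profile HMM, in log2 space.
//
// mlo, ilo: L x 20 log2 odds (emission / background) for match and insert
//           states.
// trans:    L x 7 log2 transition probabilities out of node k, columns
//           (MM, MI, MD, IM, II, DM, DD); row k feeds node k+1, row L unused.
// pep:      integer-encoded peptide, 0..19 = residue index, -1 = 'X'
//           (background emission, log-odds 0), -2 = '*' or other
//           zero-probability symbol (log-odds -Inf).
// entry:    log2 entry probability into any match state (uniform 1/L).
//
// A path enters at any match state (cost `entry`), walks M/I/D transitions
// (each M or I consumes one residue, D is silent), and may exit for free
// after any match state. Residues outside the chosen window are scored by
// the background in both model and null, so they cancel.
//
// Returns best bit score with its model/sequence coordinates (1-based,
// inclusive). Score of an empty alignment is -Inf.
// [[Rcpp::export]]
List viterbi_local_c(NumericMatrix mlo, NumericMatrix ilo,
                     NumericMatrix trans, IntegerVector pep, double entry) {
  const int L = mlo.nrow();
  const int n = pep.size();
  const double NEG = -std::numeric_limits<double>::infinity();

  // Row-rolling DP carrying each cell's alignment start (model, seq) coords.
  std::vector<double> VM(L), VI(L), VD(L), pVM(L), pVI(L), pVD(L);
  std::vector<int> MsK(L), MsI(L), IsK(L), IsI(L), DsK(L), DsI(L),
      pMsK(L), pMsI(L), pIsK(L), pIsI(L), pDsK(L), pDsI(L);

  double best = NEG;
  int b_k0 = 0, b_i0 = 0, b_k1 = 0, b_i1 = 0;

  for (int i = 0; i < n; ++i) {
    int a = pep[i];
    for (int k = 0; k < L; ++k) {
      double em = (a >= 0) ? mlo(k, a) : (a == -1 ? 0.0 : NEG);
      double ei = (a >= 0) ? ilo(k, a) : (a == -1 ? 0.0 : NEG);

      // Match state k, consuming residue i.
      double sc = entry;       // fresh local entry
      int sk = k, si = i;
      if (i > 0 && k > 0) {
        double v = pVM[k - 1] + trans(k - 1, 0);   // M->M
        if (v > sc) { sc = v; sk = pMsK[k - 1]; si = pMsI[k - 1]; }
        v = pVI[k - 1] + trans(k - 1, 3);          // I->M
        if (v > sc) { sc = v; sk = pIsK[k - 1]; si = pIsI[k - 1]; }
        v = pVD[k - 1] + trans(k - 1, 5);          // D->M
        if (v > sc) { sc = v; sk = pDsK[k - 1]; si = pDsI[k - 1]; }
      }
      VM[k] = em + sc;
      MsK[k] = sk; MsI[k] = si;

      // Insert state k (reachable only after a match/insert at node k).
      double vi = NEG; int ik = 0, ii = 0;
      if (i > 0) {
        double v = pVM[k] + trans(k, 1);           // M->I
        if (v > vi) { vi = v; ik = pMsK[k]; ii = pMsI[k]; }
        v = pVI[k] + trans(k, 4);                  // I->I
        if (v > vi) { vi = v; ik = pIsK[k]; ii = pIsI[k]; }
      }
      VI[k] = (vi == NEG) ? NEG : ei + vi;
      IsK[k] = ik; IsI[k] = ii;

      // Delete state k (silent: same row i, from node k-1 of this row).
      double vd = NEG; int dk = 0, di = 0;
      if (k > 0) {
        double v = VM[k - 1] + trans(k - 1, 2);    // M->D
        if (v > vd) { vd = v; dk = MsK[k - 1]; di = MsI[k - 1]; }
        v = VD[k - 1] + trans(k - 1, 6);           // D->D
        if (v > vd) { vd = v; dk = DsK[k - 1]; di = DsI[k - 1]; }
      }
      VD[k] = vd; DsK[k] = dk; DsI[k] = di;

      // Free exit after a match.
      if (VM[k] > best) {
        best = VM[k]; b_k0 = MsK[k]; b_i0 = MsI[k]; b_k1 = k; b_i1 = i;
      }
    }
    std::swap(VM, pVM); std::swap(VI, pVI); std::swap(VD, pVD);
    std::swap(MsK, pMsK); std::swap(MsI, pMsI);
    std::swap(IsK, pIsK); std::swap(IsI, pIsI);
    std::swap(DsK, pDsK); std::swap(DsI, pDsI);
  }

  return List::create(_["score"] = best,
                      _["model_start"] = b_k0 + 1, _["model_end"] = b_k1 + 1,
                      _["seq_start"] = b_i0 + 1, _["seq_end"] = b_i1 + 1);
}
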
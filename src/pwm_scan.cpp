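#include <Rcpp.h>
using namespace Rcpp;

// Best-single-site log-odds scan of a set of sequences with one PWM.
//
// lom: 5 x L matrix of per-position contributions for A,C,G,T and N
// (the N row holds the background expectation of the log-odds at that
// position). Scans both the given matrix and its reverse complement
// (rc passed precomputed from R). Sequences shorter than the PWM get the
// -Inf sentinel.

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

// [[Rcpp::export]]
NumericVector scan_pwm_cpp(CharacterVector seqs, NumericMatrix lom,
                           NumericMatrix lom_rc) {
  const int n = seqs.size();
  const int L = lom.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    int len = LENGTH(STRING_ELT(seqs, i));
    if (len < L) { out[i] = R_NegInf; continue; }
    std::vector<int> code(len);
    for (int p = 0; p < len; ++p) code[p] = base_code(s[p]);
    double best = R_NegInf;
    for (int p = 0; p + L <= len; ++p) {
      double fw = 0.0, rv = 0.0;
      for (int j = 0; j < L; ++j) {
        fw += lom(code[p + j], j);
        rv += lom_rc(code[p + j], j);
      }
      double m = fw > rv ? fw : rv;
      if (m > best) best = m;
    }
    out[i] = best;
  }
  return out;
}
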
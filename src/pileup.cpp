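#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

static inline int enc4(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

// Accumulate base counts and quality mass per covered reference position.
// Alignments must be on the reference's own (un-namespaced) chromosomes,
// with sequences already in aligned orientation. Insertions contribute no
// reference base; deleted positions contribute no observation.
//
// [[Rcpp::export]]
List cpp_pileup(CharacterVector ref_seqs, IntegerVector aln_chrom,
                IntegerVector aln_pos, CharacterVector aln_cigar,
                CharacterVector aln_seq, NumericVector aln_qual) {
  int nc = ref_seqs.size();
  std::vector<std::string> refs(nc);
  std::vector<std::vector<int>> counts(nc);
  std::vector<std::vector<double>> qsum(nc);
  for (int c = 0; c < nc; ++c) {
    refs[c] = as<std::string>(ref_seqs[c]);
    counts[c].assign(refs[c].size() * 4, 0);
    qsum[c].assign(refs[c].size() * 4, 0.0);
  }
  int n = aln_chrom.size();
  for (int a = 0; a < n; ++a) {
    int c = aln_chrom[a] - 1;
    if (c < 0 || c >= nc) stop("alignment %d refers to unknown chromosome", a + 1);
    std::string cig = as<std::string>(aln_cigar[a]);
    std::string seq = as<std::string>(aln_seq[a]);
    double q = aln_qual[a];
    size_t L = refs[c].size();
    long j = aln_pos[a];  // 0-based reference cursor
    size_t i = 0;         // read cursor
    size_t p = 0;
    while (p < cig.size()) {
      long len = 0;
      while (p < cig.size() && cig[p] >= '0' && cig[p] <= '9') {
        len = len * 10 + (cig[p] - '0');
        ++p;
      }
      if (p >= cig.size()) stop("malformed CIGAR in alignment %d", a + 1);
      char op = cig[p++];
      if (op == 'M') {
        if (i + len > seq.size() || j + len > (long)L)
          stop("CIGAR overruns read or reference in alignment %d", a + 1);
        for (long t = 0; t < len; ++t) {
          int b = enc4(seq[i + t]);
          if (b < 4) {
            counts[c][(size_t)(j + t) * 4 + b] += 1;
            qsum[c][(size_t)(j + t) * 4 + b] += q;
          }
        }
        i += len;
        j += len;
      } else if (op == 'I') {
        i += len;
      } else if (op == 'D') {
        j += len;
      } else {
        stop("unsupported CIGAR op '%c' in alignment %d", op, a + 1);
      }
    }
    if (i != seq.size())
      stop("CIGAR does not consume full read in alignment %d", a + 1);
  }
  // emit covered columns
  size_t total = 0;
  for (int c = 0; c < nc; ++c) {
    size_t L = refs[c].size();
    for (size_t p = 0; p < L; ++p) {
      int d = counts[c][p * 4] + counts[c][p * 4 + 1] + counts[c][p * 4 + 2] + counts[c][p * 4 + 3];
      if (d > 0) ++total;
    }
  }
  IntegerVector ochrom(total), opos(total);
  CharacterVector oref(total);
  IntegerVector cA(total), cC(total), cG(total), cT(total);
  NumericVector qA(total), qC(total), qG(total), qT(total);
  size_t k = 0;
  for (int c = 0; c < nc; ++c) {
    size_t L = refs[c].size();
    for (size_t p = 0; p < L; ++p) {
      size_t b0 = p * 4;
      int d = counts[c][b0] + counts[c][b0 + 1] + counts[c][b0 + 2] + counts[c][b0 + 3];
      if (d == 0) continue;
      ochrom[k] = c + 1;
      opos[k] = (int)p;
      oref[k] = std::string(1, refs[c][p]);
      cA[k] = counts[c][b0];     qA[k] = cA[k] ? qsum[c][b0] / cA[k] : 0.0;
      cC[k] = counts[c][b0 + 1]; qC[k] = cC[k] ? qsum[c][b0 + 1] / cC[k] : 0.0;
      cG[k] = counts[c][b0 + 2]; qG[k] = cG[k] ? qsum[c][b0 + 2] / cG[k] : 0.0;
      cT[k] = counts[c][b0 + 3]; qT[k] = cT[k] ? qsum[c][b0 + 3] / cT[k] : 0.0;
      ++k;
    }
  }
  return List::create(_["chrom"] = ochrom, _["pos"] = opos, _["ref"] = oref,
                      _["cA"] = cA, _["cC"] = cC, _["cG"] = cG, _["cT"] = cT,
                      _["qA"] = qA, _["qC"] = qC, _["qG"] = qG, _["qT"] = qT);
}
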
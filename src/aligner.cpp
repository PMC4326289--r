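#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Nucleotide encoding: A=0 C=1 G=2 T=3, anything else = 4 (never indexed,
// never matches).
static inline uint8_t enc_base(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static inline char dec_base(uint8_t b) {
  static const char tab[5] = {'A', 'C', 'G', 'T', 'N'};
  return tab[b];
}

static std::vector<uint8_t> enc_seq(const std::string &s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = enc_base(s[i]);
  return v;
}

static std::vector<uint8_t> revcomp_enc(const std::vector<uint8_t> &v) {
  std::vector<uint8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    uint8_t b = v[v.size() - 1 - i];
    r[i] = (b < 4) ? (uint8_t)(3 - b) : (uint8_t)4;
  }
  return r;
}

// ---------------------------------------------------------------------------
// Seed index: hashed k-mer -> list of (chromosome, 0-based position)
// ---------------------------------------------------------------------------

struct SeedIndex {
  int k;
  std::vector<std::string> names;               // namespaced chromosome names
  std::vector<std::vector<uint8_t>> seqs;       // encoded sequences
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> kmap;
};

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector names, int k) {
  if (k < 8 || k > 31) stop("k must be between 8 and 31");
  if (seqs.size() != names.size()) stop("seqs and names must have equal length");
  XPtr<SeedIndex> idx(new SeedIndex(), true);
  idx->k = k;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
  for (int c = 0; c < seqs.size(); ++c) {
    std::string s = as<std::string>(seqs[c]);
    idx->names.push_back(as<std::string>(names[c]));
    idx->seqs.push_back(enc_seq(s));
    const std::vector<uint8_t> &v = idx->seqs.back();
    uint64_t key = 0;
    int run = 0;
    for (int p = 0; p < (int)v.size(); ++p) {
      if (v[p] > 3) { run = 0; key = 0; continue; }
      key = ((key << 2) | v[p]) & mask;
      if (++run >= k) idx->kmap[key].push_back(std::make_pair((int32_t)c, (int32_t)(p - k + 1)));
    }
  }
  return idx;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP idx_ptr) {
  XPtr<SeedIndex> idx(idx_ptr);
  IntegerVector lens(idx->names.size());
  CharacterVector nm(idx->names.size());
  for (size_t i = 0; i < idx->names.size(); ++i) {
    nm[i] = idx->names[i];
    lens[i] = (int)idx->seqs[i].size();
  }
  return List::create(_["k"] = idx->k, _["names"] = nm, _["lengths"] = lens,
                      _["n_kmers"] = (double)idx->kmap.size());
}

// [[Rcpp::export]]
List cpp_index_kmers(SEXP idx_ptr) {
  // Dump (kmer_key, chrom, pos) triples; used only to verify index contents
  // on small genomes.
  XPtr<SeedIndex> idx(idx_ptr);
  size_t n = 0;
  for (auto &kv : idx->kmap) n += kv.second.size();
  NumericVector key(n);
  IntegerVector chrom(n), pos(n);
  size_t i = 0;
  for (auto &kv : idx->kmap) {
    for (auto &cp : kv.second) {
      key[i] = (double)kv.first;
      chrom[i] = cp.first + 1;
      pos[i] = cp.second;
      ++i;
    }
  }
  return List::create(_["key"] = key, _["chrom"] = chrom, _["pos"] = pos);
}

// ---------------------------------------------------------------------------
// Affine-gap fitting alignment (read global, reference flanks free)
// Gap of length L costs gap_open + L * gap_extend (both negative).
// ---------------------------------------------------------------------------

static const int NEG = -(1 << 29);

static inline int max3(int a, int b, int c) { return std::max(a, std::max(b, c)); }

// Score-only fitting DP with rolling rows. Fills `ends` with every reference
// end offset (exclusive, 0..n) attaining the best score.
static int fit_score_ends(const uint8_t *ref, int n, const std::vector<uint8_t> &rd,
                          int match, int mismatch, int gopen, int gext,
                          std::vector<int> *ends) {
  int m = (int)rd.size();
  std::vector<int> M0(n + 1), A0(n + 1), B0(n + 1), M1(n + 1), A1(n + 1), B1(n + 1);
  for (int j = 0; j <= n; ++j) { M0[j] = 0; A0[j] = NEG; B0[j] = NEG; }
  for (int i = 1; i <= m; ++i) {
    M1[0] = NEG;
    A1[0] = gopen + i * gext;
    B1[0] = NEG;
    uint8_t rb = rd[i - 1];
    for (int j = 1; j <= n; ++j) {
      int diag = max3(M0[j - 1], A0[j - 1], B0[j - 1]);
      int sub = (rb < 4 && rb == ref[j - 1]) ? match : mismatch;
      M1[j] = (diag <= NEG / 2) ? NEG : diag + sub;
      int a_open = std::max(M0[j], B0[j]);
      A1[j] = std::max(a_open <= NEG / 2 ? NEG : a_open + gopen + gext,
                       A0[j] <= NEG / 2 ? NEG : A0[j] + gext);
      int b_open = std::max(M1[j - 1], A1[j - 1]);
      B1[j] = std::max(b_open <= NEG / 2 ? NEG : b_open + gopen + gext,
                       B1[j - 1] <= NEG / 2 ? NEG : B1[j - 1] + gext);
    }
    std::swap(M0, M1); std::swap(A0, A1); std::swap(B0, B1);
  }
  int best = NEG;
  for (int j = 0; j <= n; ++j) best = std::max(best, std::max(M0[j], A0[j]));
  if (ends) {
    ends->clear();
    for (int j = 0; j <= n; ++j)
      if (std::max(M0[j], A0[j]) == best) ends->push_back(j);
  }
  return best;
}

// Full fitting DP over a (small) window with traceback.
struct FitAln {
  int score;
  int start;   // offset of first consumed reference base within window
  std::string cigar;
};

// Reused across candidates to avoid per-call allocation.
struct FitWorkspace {
  std::vector<int> M, A, B;
  std::vector<uint8_t> tM, tA, tB;
};

static FitAln fit_window_cigar(const uint8_t *ref, int n, const std::vector<uint8_t> &rd,
                               int match, int mismatch, int gopen, int gext,
                               FitWorkspace &ws) {
  int m = (int)rd.size();
  size_t sz = (size_t)(m + 1) * (n + 1);
  if (ws.M.size() < sz) {
    ws.M.resize(sz); ws.A.resize(sz); ws.B.resize(sz);
    ws.tM.resize(sz); ws.tA.resize(sz); ws.tB.resize(sz);
  }
  std::vector<int> &M = ws.M, &A = ws.A, &B = ws.B;
  std::vector<uint8_t> &tM = ws.tM, &tA = ws.tA, &tB = ws.tB;
  #define IX(i, j) ((size_t)(i) * (n + 1) + (j))
  for (int j = 0; j <= n; ++j) {
    M[IX(0, j)] = 0; tM[IX(0, j)] = 3;
    A[IX(0, j)] = NEG; B[IX(0, j)] = NEG;
  }
  for (int i = 1; i <= m; ++i) {
    M[IX(i, 0)] = NEG;
    B[IX(i, 0)] = NEG;
    A[IX(i, 0)] = gopen + i * gext;
    tA[IX(i, 0)] = (i == 1) ? 0 : 1;  // opened from the (virtual) start
    uint8_t rb = rd[i - 1];
    for (int j = 1; j <= n; ++j) {
      size_t d = IX(i - 1, j - 1);
      int dM = M[d], dA = A[d], dB = B[d];
      int diag = max3(dM, dA, dB);
      int sub = (rb < 4 && rb == ref[j - 1]) ? match : mismatch;
      M[IX(i, j)] = (diag <= NEG / 2) ? NEG : diag + sub;
      tM[IX(i, j)] = (diag == dM) ? 0 : (diag == dA ? 1 : 2);

      size_t u = IX(i - 1, j);
      int openA = std::max(M[u], B[u]);
      int extA = A[u];
      int vo = (openA <= NEG / 2) ? NEG : openA + gopen + gext;
      int ve = (extA <= NEG / 2) ? NEG : extA + gext;
      if (vo >= ve) { A[IX(i, j)] = vo; tA[IX(i, j)] = (openA == M[u]) ? 0 : 2; }
      else { A[IX(i, j)] = ve; tA[IX(i, j)] = 1; }

      size_t l = IX(i, j - 1);
      int openB = std::max(M[l], A[l]);
      int extB = B[l];
      int wo = (openB <= NEG / 2) ? NEG : openB + gopen + gext;
      int we = (extB <= NEG / 2) ? NEG : extB + gext;
      if (wo >= we) { B[IX(i, j)] = wo; tB[IX(i, j)] = (openB == M[l]) ? 0 : 1; }
      else { B[IX(i, j)] = we; tB[IX(i, j)] = 2; }
    }
  }
  int best = NEG, jbest = 0, sbest = 0;
  for (int j = 0; j <= n; ++j) {
    if (M[IX(m, j)] > best) { best = M[IX(m, j)]; jbest = j; sbest = 0; }
    if (A[IX(m, j)] > best) { best = A[IX(m, j)]; jbest = j; sbest = 1; }
  }
  // traceback
  std::string ops;
  int i = m, j = jbest, st = sbest;
  while (i > 0) {
    uint8_t prev;
    if (st == 0) { prev = tM[IX(i, j)]; ops.push_back('M'); --i; --j; }
    else if (st == 1) { prev = tA[IX(i, j)]; ops.push_back('I'); --i; }
    else { prev = tB[IX(i, j)]; ops.push_back('D'); --j; }
    if (prev == 3) break;
    st = prev;
  }
  #undef IX
  std::reverse(ops.begin(), ops.end());
  // run-length encode
  std::string cig;
  size_t p = 0;
  while (p < ops.size()) {
    size_t q = p;
    while (q < ops.size() && ops[q] == ops[p]) ++q;
    cig += std::to_string(q - p);
    cig.push_back(ops[p]);
    p = q;
  }
  FitAln out;
  out.score = best;
  out.start = j;
  out.cigar = cig.empty() ? "*" : cig;
  return out;
}

// ---------------------------------------------------------------------------
// Seed-and-extend alignment with unique-best-match semantics
// ---------------------------------------------------------------------------

struct Candidate {
  int chrom;
  char strand;
  int diag;   // approximate leftmost reference position
};

struct Hit {
  int chrom;
  char strand;
  int start;
  int score;
  std::string cigar;
};

static void collect_candidates(const SeedIndex &idx, const std::vector<uint8_t> &rd,
                               char strand, int max_hits_per_seed,
                               std::vector<Candidate> &out) {
  int k = idx.k;
  int m = (int)rd.size();
  if (m < k) return;
  int spacing = std::max(1, m / 4);
  std::vector<int> offsets;
  for (int p = 0; p + k <= m; p += spacing) offsets.push_back(p);
  if (offsets.empty() || offsets.back() != m - k) offsets.push_back(m - k);
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
  for (int p : offsets) {
    uint64_t key = 0;
    bool ok = true;
    for (int t = 0; t < k; ++t) {
      if (rd[p + t] > 3) { ok = false; break; }
      key = ((key << 2) | rd[p + t]) & mask;
    }
    if (!ok) continue;
    auto it = idx.kmap.find(key);
    if (it == idx.kmap.end()) continue;
    if ((int)it->second.size() > max_hits_per_seed) continue;
    for (auto &cp : it->second) {
      Candidate c;
      c.chrom = cp.first;
      c.strand = strand;
      c.diag = cp.second - p;
      out.push_back(c);
    }
  }
}

// [[Rcpp::export]]
List cpp_align_reads(SEXP idx_ptr, CharacterVector reads,
                     int match, int mismatch, int gap_open, int gap_extend,
                     int band, int max_hits_per_seed) {
  XPtr<SeedIndex> idx(idx_ptr);
  int n_reads = reads.size();
  IntegerVector chrom(n_reads, NA_INTEGER), pos(n_reads, NA_INTEGER),
      score(n_reads, NA_INTEGER), mapq(n_reads, 0), nbest(n_reads, 0),
      qlen(n_reads);
  LogicalVector mapped(n_reads, false), uniq(n_reads, false);
  CharacterVector strand(n_reads, NA_STRING), cigar(n_reads, NA_STRING);
  FitWorkspace ws;

  for (int r = 0; r < n_reads; ++r) {
    std::string rs = as<std::string>(reads[r]);
    qlen[r] = (int)rs.size();
    std::vector<uint8_t> fwd = enc_seq(rs);
    if ((int)fwd.size() < idx->k) continue;  // unmapped: shorter than a seed
    std::vector<uint8_t> rev = revcomp_enc(fwd);

    std::vector<Candidate> cands;
    collect_candidates(*idx, fwd, '+', max_hits_per_seed, cands);
    collect_candidates(*idx, rev, '-', max_hits_per_seed, cands);
    if (cands.empty()) continue;

    std::sort(cands.begin(), cands.end(), [](const Candidate &a, const Candidate &b) {
      if (a.chrom != b.chrom) return a.chrom < b.chrom;
      if (a.strand != b.strand) return a.strand < b.strand;
      return a.diag < b.diag;
    });
    cands.erase(std::unique(cands.begin(), cands.end(), [](const Candidate &a, const Candidate &b) {
      return a.chrom == b.chrom && a.strand == b.strand && a.diag == b.diag;
    }), cands.end());

    int m = (int)fwd.size();
    std::vector<Hit> hits;
    int last_chrom = -1; char last_strand = 0; int last_diag = NEG;
    for (auto &c : cands) {
      // diagonals within the band of an already-extended one land in the
      // same window; skip them
      if (c.chrom == last_chrom && c.strand == last_strand && c.diag - last_diag <= band)
        continue;
      last_chrom = c.chrom; last_strand = c.strand; last_diag = c.diag;
      const std::vector<uint8_t> &ref = idx->seqs[c.chrom];
      int L = (int)ref.size();
      int w0 = std::max(0, c.diag - band);
      int w1 = std::min(L, c.diag + m + band);
      if (w1 - w0 < 1) continue;
      const std::vector<uint8_t> &rd = (c.strand == '+') ? fwd : rev;
      FitAln fa = fit_window_cigar(ref.data() + w0, w1 - w0, rd,
                                   match, mismatch, gap_open, gap_extend, ws);
      Hit h;
      h.chrom = c.chrom;
      h.strand = c.strand;
      h.start = w0 + fa.start;
      h.score = fa.score;
      h.cigar = fa.cigar;
      hits.push_back(h);
    }
    if (hits.empty()) continue;

    // deduplicate identical loci (same chrom/strand/start), keep best score
    std::sort(hits.begin(), hits.end(), [](const Hit &a, const Hit &b) {
      if (a.chrom != b.chrom) return a.chrom < b.chrom;
      if (a.strand != b.strand) return a.strand < b.strand;
      if (a.start != b.start) return a.start < b.start;
      return a.score > b.score;
    });
    std::vector<Hit> loci;
    for (auto &h : hits) {
      if (!loci.empty() && loci.back().chrom == h.chrom &&
          loci.back().strand == h.strand && loci.back().start == h.start)
        continue;
      loci.push_back(h);
    }
    int best = NEG, second = NEG, ibest = -1, n_at_best = 0;
    for (int i = 0; i < (int)loci.size(); ++i) {
      if (loci[i].score > best) {
        second = best;
        best = loci[i].score;
        ibest = i;
        n_at_best = 1;
      } else if (loci[i].score == best) {
        ++n_at_best;
        second = best;
      } else if (loci[i].score > second) {
        second = loci[i].score;
      }
    }
    const Hit &hb = loci[ibest];
    chrom[r] = hb.chrom + 1;
    pos[r] = hb.start;
    strand[r] = std::string(1, hb.strand);
    score[r] = best;
    cigar[r] = hb.cigar;
    nbest[r] = n_at_best;
    if (n_at_best == 1) {
      mapped[r] = true;
      uniq[r] = true;
      mapq[r] = (second <= NEG / 2) ? 60 : std::min(60, std::max(0, 2 * (best - second)));
    } else {
      mapq[r] = 0;  // tie: not uniquely placeable
    }
  }
  return List::create(_["chrom"] = chrom, _["pos"] = pos, _["strand"] = strand,
                      _["score"] = score, _["mapq"] = mapq, _["cigar"] = cigar,
                      _["mapped"] = mapped, _["unique"] = uniq,
                      _["n_best"] = nbest, _["qlen"] = qlen);
}

// ---------------------------------------------------------------------------
// Exhaustive oracle: fitting DP over every position of every chromosome and
// both strands. Start positions recovered by running the DP on reversed
// sequences (an optimal alignment starting at s ends at n - s in reverse).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_oracle_align(CharacterVector ref_seqs, std::string read,
                      int match, int mismatch, int gap_open, int gap_extend) {
  std::vector<uint8_t> fwd = enc_seq(read);
  std::vector<uint8_t> rev = revcomp_enc(fwd);
  int nc = ref_seqs.size();
  int best = NEG;
  std::vector<int> lchrom, lstart;
  std::vector<char> lstrand;
  for (int pass = 0; pass < 2; ++pass) {
    for (int c = 0; c < nc; ++c) {
      std::string rs = as<std::string>(ref_seqs[c]);
      std::vector<uint8_t> ref = enc_seq(rs);
      int n = (int)ref.size();
      if (n == 0) continue;
      const std::vector<uint8_t> &rd = (pass == 0) ? fwd : rev;
      int sc = fit_score_ends(ref.data(), n, rd, match, mismatch, gap_open, gap_extend, NULL);
      if (pass == 0 && c == 0) best = sc;
      if (sc > best) best = sc;
    }
  }
  // second sweep: collect all optimal starts
  for (int pass = 0; pass < 2; ++pass) {
    for (int c = 0; c < nc; ++c) {
      std::string rs = as<std::string>(ref_seqs[c]);
      std::vector<uint8_t> ref = enc_seq(rs);
      int n = (int)ref.size();
      if (n == 0) continue;
      const std::vector<uint8_t> &rd = (pass == 0) ? fwd : rev;
      std::vector<uint8_t> ref_r(ref.rbegin(), ref.rend());
      std::vector<uint8_t> rd_r(rd.rbegin(), rd.rend());
      std::vector<int> ends;
      int sc = fit_score_ends(ref_r.data(), n, rd_r, match, mismatch, gap_open, gap_extend, &ends);
      if (sc != best) continue;
      for (int e : ends) {
        lchrom.push_back(c + 1);
        lstrand.push_back(pass == 0 ? '+' : '-');
        lstart.push_back(n - e);
      }
    }
  }
  // unique loci
  std::vector<size_t> ord(lchrom.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (lchrom[a] != lchrom[b]) return lchrom[a] < lchrom[b];
    if (lstrand[a] != lstrand[b]) return lstrand[a] < lstrand[b];
    return lstart[a] < lstart[b];
  });
  std::vector<int> uc, us;
  std::vector<std::string> ustr;
  for (size_t ii = 0; ii < ord.size(); ++ii) {
    size_t i = ord[ii];
    if (!uc.empty() && uc.back() == lchrom[i] && ustr.back()[0] == lstrand[i] &&
        us.back() == lstart[i])
      continue;
    uc.push_back(lchrom[i]);
    ustr.push_back(std::string(1, lstrand[i]));
    us.push_back(lstart[i]);
  }
  return List::create(_["score"] = best, _["chrom"] = wrap(uc),
                      _["strand"] = wrap(ustr), _["start"] = wrap(us));
}

// ---------------------------------------------------------------------------
// Sequencing-error injection (uses R's RNG: deterministic under set.seed)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_inject_errors(CharacterVector reads, double error_rate) {
  int n = reads.size();
  CharacterVector out(n);
  IntegerVector nerr(n);
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(reads[i]);
    int e = 0;
    if (error_rate > 0) {
      for (size_t p = 0; p < s.size(); ++p) {
        if (unif_rand() < error_rate) {
          uint8_t cur = enc_base(s[p]);
          int shift = 1 + (int)(unif_rand() * 3.0);
          if (shift > 3) shift = 3;
          uint8_t nb = (cur < 4) ? (uint8_t)((cur + shift) % 4) : (uint8_t)(unif_rand() * 4.0);
          s[p] = bases[nb];
          ++e;
        }
      }
    }
    out[i] = s;
    nerr[i] = e;
  }
  return List::create(_["seq"] = out, _["n_err"] = nerr);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::vector<uint8_t> v = revcomp_enc(enc_seq(s));
    std::string r(v.size(), 'N');
    for (size_t p = 0; p < v.size(); ++p) r[p] = dec_base(v[p]);
    out[i] = r;
  }
  return out;
}
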
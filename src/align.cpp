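#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
using namespace Rcpp;

// Global pairwise alignment, Gotoh affine-gap recursion.
// Scoring is fixed package-wide: match +1, mismatch -1, a gap run of
// length g costs 2 + (g - 1) (open 2 on the first gap base, extend 1).
// Tie-breaks are deterministic: diagonal (match/mismatch) is preferred
// over a gap-in-read (deletion), which is preferred over a gap-in-ref
// (insertion); within a gap state, closing the gap is preferred over
// extending it. The testthat suite holds an independent R implementation
// of the same conventions to the exact same tallies.

static const int MATCH = 1;
static const int MISMATCH = -1;
static const int GAP_OPEN = 2;   // cost of the first base of a gap
static const int GAP_EXT = 1;    // cost of each further base
static const int NEG = -100000000;

static inline int subScore(char a, char b) {
  return (a == b) ? MATCH : MISMATCH;
}

// mask: reference positions scored as wildcards (always MATCH) — used for
// the degenerate (saturated) codon windows, where the library reference
// is any NNK codon rather than the wild-type bases. An empty mask means
// no wildcards.

struct AlnResult {
  int score;
  // per reference position: the read character aligned to it, '-' if deleted
  std::string refAligned;
  // insertion lengths keyed by reference boundary (before ref position b)
  std::vector<int> insAt; // size n+1
  // the inserted read characters at each boundary, in read order
  std::vector<std::string> insChars; // size n+1
};

// Full Gotoh DP with traceback. ref length n (rows), read length m (cols).
static AlnResult gotohAlign(const std::string &ref, const std::string &read,
                            const std::vector<bool> &mask) {
  const int n = (int) ref.size();
  const int m = (int) read.size();
  const int W = m + 1;
  std::vector<int> M((n + 1) * W), X((n + 1) * W), Y((n + 1) * W);

  M[0] = 0; X[0] = NEG; Y[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    M[j] = NEG;
    X[j] = NEG;
    Y[j] = -(GAP_OPEN + GAP_EXT * (j - 1));
  }
  for (int i = 1; i <= n; ++i) {
    M[i * W] = NEG;
    X[i * W] = -(GAP_OPEN + GAP_EXT * (i - 1));
    Y[i * W] = NEG;
  }
  for (int i = 1; i <= n; ++i) {
    const char rc = ref[i - 1];
    const bool wild = !mask.empty() && mask[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int d = (i - 1) * W + (j - 1);
      int best = M[d];
      if (X[d] > best) best = X[d];
      if (Y[d] > best) best = Y[d];
      M[i * W + j] = best + (wild ? MATCH : subScore(rc, read[j - 1]));
      const int up = (i - 1) * W + j;
      int xo = M[up] - GAP_OPEN, xe = X[up] - GAP_EXT;
      X[i * W + j] = (xo >= xe) ? xo : xe;
      const int lf = i * W + (j - 1);
      int yo = M[lf] - GAP_OPEN, ye = Y[lf] - GAP_EXT;
      Y[i * W + j] = (yo >= ye) ? yo : ye;
    }
  }

  AlnResult res;
  res.refAligned.assign(n, '-');
  res.insAt.assign(n + 1, 0);
  res.insChars.assign(n + 1, std::string());

  int i = n, j = m;
  int state; // 0 = M, 1 = X (del), 2 = Y (ins)
  const int e = n * W + m;
  if (M[e] >= X[e] && M[e] >= Y[e]) { state = 0; res.score = M[e]; }
  else if (X[e] >= Y[e]) { state = 1; res.score = X[e]; }
  else { state = 2; res.score = Y[e]; }

  while (i > 0 || j > 0) {
    if (state == 0) {
      // diagonal step consuming ref[i-1], read[j-1]
      res.refAligned[i - 1] = read[j - 1];
      const int d = (i - 1) * W + (j - 1);
      int best = M[d];
      if (X[d] > best) best = X[d];
      if (Y[d] > best) best = Y[d];
      int next;
      if (M[d] == best) next = 0; else if (X[d] == best) next = 1; else next = 2;
      --i; --j;
      state = next;
      if (i == 0 && j == 0) break;
      if (i == 0) state = 2;
      if (j == 0) state = 1;
    } else if (state == 1) {
      // gap in read: ref[i-1] deleted
      const int up = (i - 1) * W + j;
      int cur = X[i * W + j];
      int next = (M[up] - GAP_OPEN == cur) ? 0 : 1;
      --i;
      state = next;
      if (i == 0 && j > 0) state = 2;
      if (i == 0 && j == 0) break;
    } else {
      // gap in ref: read[j-1] inserted before ref position i
      res.insAt[i] += 1;
      res.insChars[i].insert(res.insChars[i].begin(), read[j - 1]);
      const int lf = i * W + (j - 1);
      int cur = Y[i * W + j];
      int next = (M[lf] - GAP_OPEN == cur) ? 0 : 2;
      --j;
      state = next;
      if (j == 0 && i > 0) state = 1;
      if (i == 0 && j == 0) break;
    }
  }
  return res;
}

// score of pairing read char c with reference position p (wildcard
// windows always match)
static inline int colScore(char c, int p, const std::string &ref,
                           const std::vector<bool> &inWin) {
  if (inWin[p]) return MATCH;
  return (c == ref[p]) ? MATCH : MISMATCH;
}

// Can a deletion run [p1, p2] slide, through score-neutral single steps,
// to overlap a degenerate window? Gap placement inside the wildcard
// windows is score-ambiguous, so the window-disruption flag must consider
// every equal-score placement reachable by sliding.
static bool delCanReachWindow(int p1, int p2, const std::string &refAligned,
                              const std::string &ref,
                              const std::vector<bool> &inWin) {
  const int n = (int) ref.size();
  int q1 = p1, q2 = p2;
  for (int step = 0; step < 3 * n; ++step) { // walk left
    if (q1 <= 0) break;
    char c = refAligned[q1 - 1];
    if (c == '-') break; // adjacent gap: stop conservatively
    if (colScore(c, q1 - 1, ref, inWin) != colScore(c, q2, ref, inWin))
      break;
    --q1; --q2;
    bool hit = false;
    for (int p = q1; p <= q2; ++p) if (inWin[p]) hit = true;
    if (hit) return true;
  }
  q1 = p1; q2 = p2;
  for (int step = 0; step < 3 * n; ++step) { // walk right
    if (q2 >= n - 1) break;
    char c = refAligned[q2 + 1];
    if (c == '-') break;
    if (colScore(c, q2 + 1, ref, inWin) != colScore(c, q1, ref, inWin))
      break;
    ++q1; ++q2;
    bool hit = false;
    for (int p = q1; p <= q2; ++p) if (inWin[p]) hit = true;
    if (hit) return true;
  }
  return false;
}

// Same question for an insertion block at reference boundary b: slide the
// block one column at a time, rotating its characters, as long as the
// exchanged pairings score equally.
static bool insCanReachWindow(int b, std::string block,
                              const std::string &refAligned,
                              const std::string &ref,
                              const std::vector<bool> &inWin,
                              const IntegerVector &winStart,
                              const IntegerVector &winEnd) {
  const int n = (int) ref.size();
  const int nw = winStart.size();
  auto interior = [&](int bnd) {
    for (int w = 0; w < nw; ++w)
      if (bnd > winStart[w] && bnd < winEnd[w]) return true;
    return false;
  };
  // walk left
  {
    int bb = b;
    std::string blk = block;
    std::string cols = refAligned;
    for (int step = 0; step < 3 * n; ++step) {
      if (bb <= 0) break;
      char a = cols[bb - 1];
      if (a == '-') break;
      char ik = blk.back();
      if (colScore(ik, bb - 1, ref, inWin) != colScore(a, bb - 1, ref, inWin))
        break;
      blk.pop_back();
      blk.insert(blk.begin(), a);
      cols[bb - 1] = ik;
      --bb;
      if (interior(bb)) return true;
    }
  }
  // walk right
  {
    int bb = b;
    std::string blk = block;
    std::string cols = refAligned;
    for (int step = 0; step < 3 * n; ++step) {
      if (bb >= n) break;
      char c = cols[bb];
      if (c == '-') break;
      char i1 = blk[0];
      if (colScore(i1, bb, ref, inWin) != colScore(c, bb, ref, inWin))
        break;
      blk.erase(blk.begin());
      blk.push_back(c);
      cols[bb] = i1;
      ++bb;
      if (interior(bb)) return true;
    }
  }
  return false;
}

static inline int baseIndex(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  default: return -1;
  }
}

// Analyze reads against a reference amplicon: align, tally errors by type
// (excluding the targeted codon windows), flag frameshifts and
// window-disrupting indels, and extract the read bases over each window.
//
// winStart/winEnd: 0-based half-open nucleotide intervals (sorted,
// non-overlapping). frameOffset: 0-based first coding base. Reads of equal
// length with at most 2 mismatches take a gap-free fast path that is
// provably score-optimal under this scoring (any gapped alignment of
// equal-length sequences scores <= L - 5).
// [[Rcpp::export]]
List cs_analyze_reads(CharacterVector reads, std::string ref,
                      IntegerVector winStart, IntegerVector winEnd,
                      int frameOffset) {
  const int n = (int) ref.size();
  const int nr = reads.size();
  const int nw = winStart.size();
  const int codingEnd = frameOffset + 3 * ((n - frameOffset) / 3);

  std::vector<bool> inWin(n, false);
  int winBases = 0;
  for (int w = 0; w < nw; ++w)
    for (int p = winStart[w]; p < winEnd[w]; ++p) { inWin[p] = true; ++winBases; }

  IntegerVector score(nr), nSub(nr), delBases(nr), insBases(nr), basesAnalyzed(nr);
  LogicalVector frameshift(nr), indelInWindow(nr);
  NumericVector identity(nr);
  CharacterVector windowSeq(nr);
  IntegerMatrix subMat(nr, 16);

  std::string wseq(3 * nw > 0 ? winBases : 0, 'N');

  for (int r = 0; r < nr; ++r) {
    const char *rp = CHAR(STRING_ELT(reads, r));
    std::string read(rp);
    int m = (int) read.size();
    if (m == 0) stop("empty read at index %d", r + 1);

    std::string refAligned;
    std::vector<int> insAt;
    std::vector<std::string> insChars;
    int sc;
    bool fast = false;
    if (m == n) {
      // mismatches outside the degenerate windows; the gap-free alignment
      // is provably optimal when h <= 2 (any gapped alignment of
      // equal-length sequences scores at most L - 5 here)
      int h = 0;
      for (int p = 0; p < n; ++p)
        if (!inWin[p] && read[p] != ref[p]) ++h;
      if (h <= 2) { fast = true; sc = n - 2 * h; }
    }
    if (fast) {
      refAligned = read;
      insAt.assign(n + 1, 0);
      insChars.assign(n + 1, std::string());
    } else {
      AlnResult a = gotohAlign(ref, read, inWin);
      refAligned.swap(a.refAligned);
      insAt.swap(a.insAt);
      insChars.swap(a.insChars);
      sc = a.score;
    }

    int subs = 0, dels = 0, inss = 0, matches = 0, codingIndel = 0;
    bool winHit = false;
    int wpos = 0;
    for (int p = 0; p < n; ++p) {
      const char c = refAligned[p];
      if (inWin[p]) wseq[wpos++] = c;
      if (c == '-') {
        ++dels;
        if (inWin[p]) winHit = true;
        if (p >= frameOffset && p < codingEnd) ++codingIndel;
      } else if (c == ref[p] || inWin[p]) {
        ++matches; // window positions are degenerate: any base matches
      } else {
        const int bi = baseIndex(ref[p]), bj = baseIndex(c);
        if (bi >= 0 && bj >= 0) { ++subs; subMat(r, 4 * bi + bj) += 1; }
      }
    }
    for (int b = 0; b <= n; ++b) {
      const int k = insAt[b];
      if (k == 0) continue;
      inss += k;
      if (b > frameOffset && b < codingEnd) codingIndel += k;
      for (int w = 0; w < nw; ++w)
        if (b > winStart[w] && b < winEnd[w]) winHit = true;
      if (!winHit && nw > 0 &&
          insCanReachWindow(b, insChars[b], refAligned, ref, inWin,
                            winStart, winEnd))
        winHit = true;
    }
    // deletions that can slide into a window at equal score also disrupt it
    if (!winHit && dels > 0 && nw > 0) {
      int p = 0;
      while (p < n) {
        if (refAligned[p] == '-') {
          int p2 = p;
          while (p2 + 1 < n && refAligned[p2 + 1] == '-') ++p2;
          if (delCanReachWindow(p, p2, refAligned, ref, inWin)) {
            winHit = true;
            break;
          }
          p = p2 + 1;
        } else ++p;
      }
    }

    score[r] = sc;
    nSub[r] = subs;
    delBases[r] = dels;
    insBases[r] = inss;
    basesAnalyzed[r] = n - winBases;
    frameshift[r] = (codingIndel > 0) && (codingIndel % 3 != 0);
    indelInWindow[r] = winHit;
    identity[r] = (double) matches / (double) n;
    windowSeq[r] = wseq;
  }

  return List::create(
    _["score"] = score, _["nSub"] = nSub, _["delBases"] = delBases,
    _["insBases"] = insBases, _["basesAnalyzed"] = basesAnalyzed,
    _["frameshift"] = frameshift, _["indelInWindow"] = indelInWindow,
    _["identity"] = identity, _["windowSeq"] = windowSeq,
    _["subMat"] = subMat);
}

// Single-pair alignment returning the two gapped strings (for inspection
// and for the test oracle comparisons).
// [[Rcpp::export]]
List cs_pair_align(std::string read, std::string ref) {
  if (read.empty() || ref.empty()) stop("empty sequence");
  AlnResult a = gotohAlign(ref, read, std::vector<bool>());
  // rebuild the two gapped strings from refAligned + insAt
  std::string ar, rd;
  for (int b = 0; b <= (int) ref.size(); ++b) {
    for (int k = 0; k < a.insAt[b]; ++k) { ar.push_back('-'); rd.push_back('?'); }
    if (b < (int) ref.size()) {
      ar.push_back(ref[b]);
      rd.push_back(a.refAligned[b]);
    }
  }
  // fill inserted read characters: walk the read once
  size_t ri = 0;
  for (size_t p = 0; p < rd.size(); ++p) {
    if (rd[p] == '-') continue;
    if (rd[p] == '?') { rd[p] = read[ri++]; } else { ri++; }
  }
  return List::create(_["ref"] = ar, _["read"] = rd, _["score"] = a.score);
}

static inline char transitionOf(char c) {
  switch (c) {
  case 'A': return 'G'; case 'G': return 'A';
  case 'C': return 'T'; case 'T': return 'C';
  }
  return c;
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// Inject substitution, deletion and insertion errors into template reads.
// Rates are per-base (expected error bases per template base); indel event
// rates are derived from the per-base rates and the mean event length.
// tsProb is the probability that a substitution is a transition.
// Uses the R RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List cs_mutate_reads(CharacterVector templates,
                     NumericVector subRate, NumericVector delRate,
                     NumericVector insRate, double tsProb,
                     IntegerVector delLens, NumericVector delLenProbs,
                     IntegerVector insLens, NumericVector insLenProbs,
                     int frameOffset) {
  const int nr = templates.size();
  double meanDelLen = 0.0, meanInsLen = 0.0;
  for (int k = 0; k < delLens.size(); ++k) meanDelLen += delLens[k] * delLenProbs[k];
  for (int k = 0; k < insLens.size(); ++k) meanInsLen += insLens[k] * insLenProbs[k];

  CharacterVector out(nr);
  IntegerVector nSub(nr), nDel(nr), nIns(nr);
  LogicalVector frameshift(nr);

  for (int r = 0; r < nr; ++r) {
    std::string tmpl(CHAR(STRING_ELT(templates, r)));
    const int L = (int) tmpl.size();
    const int codingEnd = frameOffset + 3 * ((L - frameOffset) / 3);
    std::vector<bool> deleted(L, false);
    std::vector<std::string> insBefore(L + 1);
    int subs = 0, delB = 0, insB = 0, codingIndel = 0;

    // deletions
    if (delRate[r] > 0) {
      int nEv = (int) R::rbinom((double) L, delRate[r] / meanDelLen);
      for (int e = 0; e < nEv; ++e) {
        int u = (int) (R::unif_rand() * L); if (u >= L) u = L - 1;
        double x = R::unif_rand(); int len = delLens[delLens.size() - 1];
        double acc = 0.0;
        for (int k = 0; k < delLens.size(); ++k) {
          acc += delLenProbs[k];
          if (x <= acc) { len = delLens[k]; break; }
        }
        for (int p = u; p < std::min(u + len, L); ++p) {
          if (!deleted[p]) {
            deleted[p] = true; ++delB;
            if (p >= frameOffset && p < codingEnd) ++codingIndel;
          }
        }
      }
    }
    // insertions
    if (insRate[r] > 0) {
      int nEv = (int) R::rbinom((double) L, insRate[r] / meanInsLen);
      for (int e = 0; e < nEv; ++e) {
        int u = (int) (R::unif_rand() * (L + 1)); if (u > L) u = L;
        double x = R::unif_rand(); int len = insLens[insLens.size() - 1];
        double acc = 0.0;
        for (int k = 0; k < insLens.size(); ++k) {
          acc += insLenProbs[k];
          if (x <= acc) { len = insLens[k]; break; }
        }
        for (int k = 0; k < len; ++k) {
          int b = (int) (R::unif_rand() * 4); if (b > 3) b = 3;
          insBefore[u].push_back(BASES[b]);
        }
        insB += len;
        if (u > frameOffset && u < codingEnd) codingIndel += len;
      }
    }
    // substitutions (on surviving template positions)
    if (subRate[r] > 0) {
      int nEv = (int) R::rbinom((double) L, subRate[r]);
      for (int e = 0; e < nEv; ++e) {
        int u = (int) (R::unif_rand() * L); if (u >= L) u = L - 1;
        if (deleted[u]) continue;
        char c = tmpl[u];
        int bi = baseIndex(c);
        if (bi < 0) continue;
        char nc;
        if (R::unif_rand() < tsProb) {
          nc = transitionOf(c);
        } else {
          // one of the two transversion partners, equal odds
          char tv1, tv2;
          if (c == 'A' || c == 'G') { tv1 = 'C'; tv2 = 'T'; }
          else { tv1 = 'A'; tv2 = 'G'; }
          nc = (R::unif_rand() < 0.5) ? tv1 : tv2;
        }
        if (nc != tmpl[u]) { tmpl[u] = nc; ++subs; }
      }
    }

    std::string res;
    res.reserve(L + insB);
    for (int p = 0; p <= L; ++p) {
      if (!insBefore[p].empty()) res += insBefore[p];
      if (p < L && !deleted[p]) res.push_back(tmpl[p]);
    }
    out[r] = res;
    nSub[r] = subs; nDel[r] = delB; nIns[r] = insB;
    frameshift[r] = (codingIndel > 0) && (codingIndel % 3 != 0);
  }

  return List::create(_["read"] = out, _["nSub"] = nSub,
                      _["nDelBases"] = nDel, _["nInsBases"] = nIns,
                      _["frameshift"] = frameshift);
}
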
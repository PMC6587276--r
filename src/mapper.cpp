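// Gap-free k-mismatch short-read mapping.
//
// Two entry points share the same placement semantics (full-length, no
// indels, Hamming distance <= max_mm, both strands, N never matches):
//   * pigeonhole_map_cpp  -- production path: split each read into
//     (max_mm + 1) disjoint seeds, exact-match seeds via a reference k-mer
//     index, verify candidates by full Hamming comparison. Lossless for
//     substitution-only search.
//   * brute_scan_cpp      -- reference path: naive scan over every offset
//     and both strands; used as the independent oracle in tests.
// Plus junction_scan_cpp: terminus-anchored chimeric-read detection.

#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static inline int code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  }
  return -1;
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (char &c : r) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'T': c = 'A'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    default:  c = 'N'; break;
    }
  }
  return r;
}

// Hamming distance with early exit once max_mm is exceeded.
// An ambiguous base (N) on either side counts as a mismatch, even N vs N.
static inline int hamming_le(const char *a, const char *b, int L, int max_mm) {
  int mm = 0;
  for (int i = 0; i < L; ++i) {
    char x = a[i], y = b[i];
    if (x != y || x == 'N' || y == 'N') {
      if (++mm > max_mm) return mm;
    }
  }
  return mm;
}

struct SeedIndex {
  std::unordered_map<uint64_t, std::vector<int> > pos;
};

// Index every s-mer of the reference (s <= 16, 2-bit encoded); k-mers
// containing non-ACGT characters are skipped (they can never seed a match).
static void build_index(const std::string &ref, int s, SeedIndex &idx) {
  const int G = (int) ref.size();
  if (G < s) return;
  const uint64_t mask = (s < 32) ? ((1ULL << (2 * s)) - 1) : ~0ULL;
  uint64_t key = 0;
  int valid = 0;
  for (int i = 0; i < G; ++i) {
    int c = code(ref[i]);
    if (c < 0) { valid = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t) c) & mask;
    if (valid < s) ++valid;
    if (valid == s) idx.pos[key].push_back(i - s + 1);
  }
}

// [[Rcpp::export]]
DataFrame pigeonhole_map_cpp(CharacterVector reads, CharacterVector ref_seqs,
                             int max_mm) {
  const int nref = ref_seqs.size();
  std::vector<std::string> refs(nref);
  for (int j = 0; j < nref; ++j) refs[j] = as<std::string>(ref_seqs[j]);

  std::vector<int> out_read, out_ref, out_start, out_strand, out_mm;
  // (ref index, seed length) -> index, built lazily
  std::map<std::pair<int, int>, SeedIndex> cache;

  const int n = reads.size();
  const int nseed = max_mm + 1;
  for (int i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    const int L = (int) fwd.size();
    if (L == 0) continue;
    bool hasN = false;
    for (char c : fwd) if (!is_acgt(c)) { hasN = true; break; }
    if (hasN) continue;  // ambiguous reads are never mapped
    std::string rev = revcomp(fwd);
    int s = L / nseed;
    if (s > 16) s = 16;
    if (s < 1) continue;  // read shorter than one seed per allowed mismatch

    for (int j = 0; j < nref; ++j) {
      const std::string &R = refs[j];
      const int G = (int) R.size();
      if (L > G) continue;
      auto keyp = std::make_pair(j, s);
      auto it = cache.find(keyp);
      if (it == cache.end()) {
        it = cache.emplace(keyp, SeedIndex()).first;
        build_index(R, s, it->second);
      }
      SeedIndex &idx = it->second;

      for (int strand = 0; strand < 2; ++strand) {
        const std::string &q = strand ? rev : fwd;
        std::vector<int> cand;
        for (int k = 0; k < nseed; ++k) {
          int off = (int) (((long long) k * L) / nseed);
          if (off + s > L) off = L - s;
          uint64_t key = 0;
          bool ok = true;
          for (int t = 0; t < s; ++t) {
            int c = code(q[off + t]);
            if (c < 0) { ok = false; break; }
            key = (key << 2) | (uint64_t) c;
          }
          if (!ok) continue;
          auto f = idx.pos.find(key);
          if (f == idx.pos.end()) continue;
          for (int p : f->second) {
            int st = p - off;
            if (st >= 0 && st + L <= G) cand.push_back(st);
          }
        }
        std::sort(cand.begin(), cand.end());
        cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
        for (int st : cand) {
          int mm = hamming_le(q.c_str(), R.c_str() + st, L, max_mm);
          if (mm <= max_mm) {
            out_read.push_back(i + 1);
            out_ref.push_back(j + 1);
            out_start.push_back(st);
            out_strand.push_back(strand);
            out_mm.push_back(mm);
          }
        }
      }
    }
  }
  return DataFrame::create(_["read"] = out_read, _["ref"] = out_ref,
                           _["start"] = out_start, _["strand"] = out_strand,
                           _["mismatches"] = out_mm);
}

// [[Rcpp::export]]
DataFrame brute_scan_cpp(CharacterVector reads, CharacterVector ref_seqs,
                         int max_mm) {
  const int nref = ref_seqs.size();
  std::vector<std::string> refs(nref);
  for (int j = 0; j < nref; ++j) refs[j] = as<std::string>(ref_seqs[j]);

  std::vector<int> out_read, out_ref, out_start, out_strand, out_mm;
  const int n = reads.size();
  for (int i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    const int L = (int) fwd.size();
    if (L == 0) continue;
    bool hasN = false;
    for (char c : fwd) if (!is_acgt(c)) { hasN = true; break; }
    if (hasN) continue;
    std::string rev = revcomp(fwd);
    for (int j = 0; j < nref; ++j) {
      const std::string &R = refs[j];
      const int G = (int) R.size();
      if (L > G) continue;
      for (int strand = 0; strand < 2; ++strand) {
        const std::string &q = strand ? rev : fwd;
        for (int st = 0; st + L <= G; ++st) {
          int mm = hamming_le(q.c_str(), R.c_str() + st, L, max_mm);
          if (mm <= max_mm) {
            out_read.push_back(i + 1);
            out_ref.push_back(j + 1);
            out_start.push_back(st);
            out_strand.push_back(strand);
            out_mm.push_back(mm);
          }
        }
      }
    }
  }
  return DataFrame::create(_["read"] = out_read, _["ref"] = out_ref,
                           _["start"] = out_start, _["strand"] = out_strand,
                           _["mismatches"] = out_mm);
}

// Chimeric-read scan: for each read (and its reverse complement) find the
// longest prefix/suffix anchored at a TE consensus terminus.
//   side 0 ("5prime"): read suffix of length m matches TE[0, m)   -> flank
//     is the read prefix (genomic sequence joined to the TE 5' end).
//   side 1 ("3prime"): read prefix of length m matches TE[Lte-m, Lte) ->
//     flank is the read suffix.
// Reports the interpretation with maximal TE match length; ties prefer
// forward orientation, then side 0 (deterministic).
// [[Rcpp::export]]
DataFrame junction_scan_cpp(CharacterVector reads, std::string te,
                            int min_te_match, int min_flank, int max_mm_te) {
  const int Lte = (int) te.size();
  std::vector<int> o_idx, o_orient, o_side, o_m, o_mm;
  const int n = reads.size();
  for (int i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    const int L = (int) fwd.size();
    if (L < min_te_match + min_flank) continue;
    int best_m = -1, best_orient = 0, best_side = 0, best_mm = 0;
    for (int orient = 0; orient < 2; ++orient) {
      std::string q = orient ? revcomp(fwd) : fwd;
      // side 0: suffix anchored at TE start; smallest flank = largest m
      for (int b = min_flank; b <= L - min_te_match; ++b) {
        int m = L - b;
        if (m > Lte) continue;
        int mm = hamming_le(q.c_str() + b, te.c_str(), m, max_mm_te);
        if (mm <= max_mm_te) {
          if (m > best_m) { best_m = m; best_orient = orient; best_side = 0; best_mm = mm; }
          break;
        }
      }
      // side 1: prefix anchored at TE end; scan m downward
      int mtop = std::min(L - min_flank, Lte);
      for (int m = mtop; m >= min_te_match; --m) {
        int mm = hamming_le(q.c_str(), te.c_str() + (Lte - m), m, max_mm_te);
        if (mm <= max_mm_te) {
          if (m > best_m) { best_m = m; best_orient = orient; best_side = 1; best_mm = mm; }
          break;
        }
      }
    }
    if (best_m >= min_te_match) {
      o_idx.push_back(i + 1);
      o_orient.push_back(best_orient);
      o_side.push_back(best_side);
      o_m.push_back(best_m);
      o_mm.push_back(best_mm);
    }
  }
  return DataFrame::create(_["read"] = o_idx, _["orient"] = o_orient,
                           _["side"] = o_side, _["te_match_len"] = o_m,
                           _["mm_te"] = o_mm);
}
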
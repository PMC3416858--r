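#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Exhaustive substitution-only alignment of short reads against a single
// reference string on both strands. Positions overlapping any non-ACGT
// reference base (e.g. the N spacers between concatenated nanochromosomes)
// are never reported. Candidate generation uses a pigeonhole seed scheme:
// with a mismatch budget k, a read is split into k+1 disjoint seeds, at
// least one of which must match exactly at any admissible site.

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (std::string::size_type i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

struct SeedIndex {
  int s;
  std::unordered_map<uint64_t, std::vector<int> > pos;
};

static void build_index(const std::string &ref, int s, SeedIndex &idx) {
  idx.s = s;
  uint64_t key = 0;
  uint64_t mask = (s >= 32) ? ~0ULL : ((1ULL << (2 * s)) - 1);
  int run = 0;
  for (size_t i = 0; i < ref.size(); ++i) {
    int c = base_code(ref[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    ++run;
    if (run >= s) idx.pos[key].push_back((int)i - s + 1);
  }
}

// Count mismatches of q against ref[start, start+L); returns -1 if the
// window leaves the reference or touches a non-ACGT base, else the count
// (capped search stops once count exceeds max_mm, returning max_mm + 1).
static int verify(const std::string &q, const std::string &ref,
                  int start, int max_mm) {
  int L = (int)q.size();
  if (start < 0 || start + L > (int)ref.size()) return -1;
  int mm = 0;
  for (int i = 0; i < L; ++i) {
    char rc = ref[start + i];
    if (base_code(rc) < 0) return -1;
    if (rc != q[i]) {
      if (++mm > max_mm) return max_mm + 1;
    }
  }
  return mm;
}

// [[Rcpp::export]]
DataFrame cpp_align_all(CharacterVector reads, std::string ref,
                        int max_mm, int seed_cap = 12) {
  std::unordered_map<int, SeedIndex> indices;
  std::vector<int> out_read, out_start, out_mm;
  std::vector<int> out_strand; // 0 = plus, 1 = minus

  int n = reads.size();
  int refsize = (int)ref.size();
  std::vector<int> cand;

  for (int i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    int L = (int)fwd.size();
    if (L < 1) continue;
    for (int st = 0; st < 2; ++st) {
      std::string q = (st == 0) ? fwd : revcomp_str(fwd);
      bool valid = true;
      for (int j = 0; j < L; ++j)
        if (base_code(q[j]) < 0) { valid = false; break; }
      if (!valid) continue;

      cand.clear();
      int nseg = max_mm + 1;
      int s = std::min(seed_cap, L / nseg);
      if (s >= 4) {
        std::unordered_map<int, SeedIndex>::iterator it = indices.find(s);
        if (it == indices.end()) {
          build_index(ref, s, indices[s]);
          it = indices.find(s);
        }
        const SeedIndex &idx = it->second;
        for (int seg = 0; seg < nseg; ++seg) {
          int off = seg * s;
          uint64_t key = 0;
          for (int j = 0; j < s; ++j)
            key = (key << 2) | (uint64_t)base_code(q[off + j]);
          std::unordered_map<uint64_t, std::vector<int> >::const_iterator
            hit = idx.pos.find(key);
          if (hit == idx.pos.end()) continue;
          const std::vector<int> &pp = hit->second;
          for (size_t t = 0; t < pp.size(); ++t) {
            int start = pp[t] - off;
            if (start >= 0 && start + L <= refsize) cand.push_back(start);
          }
        }
        std::sort(cand.begin(), cand.end());
        cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      } else {
        // budget too large relative to read length for seeding: full scan
        for (int start = 0; start + L <= refsize; ++start)
          cand.push_back(start);
      }

      for (size_t t = 0; t < cand.size(); ++t) {
        int mm = verify(q, ref, cand[t], max_mm);
        if (mm >= 0 && mm <= max_mm) {
          out_read.push_back(i + 1);
          out_start.push_back(cand[t]);
          out_strand.push_back(st);
          out_mm.push_back(mm);
        }
      }
    }
  }

  int m = (int)out_read.size();
  CharacterVector strand(m);
  for (int i = 0; i < m; ++i) strand[i] = out_strand[i] == 0 ? "+" : "-";
  return DataFrame::create(
    _["read"] = wrap(out_read),
    _["start"] = wrap(out_start),
    _["strand"] = strand,
    _["mismatches"] = wrap(out_mm),
    _["stringsAsFactors"] = false);
}

// Locate the 3' sequencing adapter in each read and return the insert
// (the prefix preceding the adapter). The rightmost position at which the
// remainder of the read matches a prefix of the adapter exactly, over at
// least min_overlap bases, wins; reads with no admissible match give NA.
// [[Rcpp::export]]
CharacterVector cpp_trim_adapter(CharacterVector reads, std::string adapter,
                                 int min_overlap) {
  int n = reads.size();
  int alen = (int)adapter.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string r = as<std::string>(reads[i]);
    int rlen = (int)r.size();
    int found = -1;
    for (int p = rlen - min_overlap; p >= 0; --p) {
      int m = std::min(alen, rlen - p);
      bool ok = true;
      for (int j = 0; j < m; ++j)
        if (r[p + j] != adapter[j]) { ok = false; break; }
      if (ok) { found = p; break; }
    }
    if (found < 0) out[i] = NA_STRING;
    else out[i] = r.substr(0, found);
  }
  return out;
}
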
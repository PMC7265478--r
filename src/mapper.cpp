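// k-mer index and ungapped seed-and-extend read mapper.
//
// Genomes are indexed on the forward strand with 2-bit packed k-mers
// (k <= 31); windows containing non-ACGT characters are skipped, so IUPAC
// ambiguity codes never seed a match. Reads are queried on both strands.
// Extension is ungapped along the seed diagonal over the full read/genome
// overlap; the best hit per genome is kept (most matches, then highest
// identity, then leftmost, then forward strand).

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <map>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

struct KmerIndex {
  int k;
  std::vector<std::string> seqs;
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> idx;
};

inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

inline char base_comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
  }
  return 'N';
}

// Apply f(packed_kmer, start) to every ACGT-only k-mer of s.
template <typename F>
void for_each_kmer(const std::string& s, int k, F f) {
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t v = 0;
  int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int c = base_code(s[i]);
    if (c < 0) {
      run = 0;
      v = 0;
      continue;
    }
    v = ((v << 2) | static_cast<uint64_t>(c)) & mask;
    if (++run >= k) f(v, static_cast<int32_t>(i + 1 - k));
  }
}

// Pack an ACGT-only string; returns false if it contains other characters.
bool pack_kmer(const std::string& s, uint64_t* out) {
  uint64_t v = 0;
  for (char c : s) {
    int x = base_code(c);
    if (x < 0) return false;
    v = (v << 2) | static_cast<uint64_t>(x);
  }
  *out = v;
  return true;
}

KmerIndex* get_index(SEXP ptr) {
  Rcpp::XPtr<KmerIndex> p(ptr);
  if (!p) stop("stale k-mer index pointer");
  return p.get();
}

}  // namespace

// [[Rcpp::export]]
SEXP kmer_index_build(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  XPtr<KmerIndex> p(new KmerIndex(), true);
  p->k = k;
  p->seqs.reserve(seqs.size());
  for (R_xlen_t g = 0; g < seqs.size(); ++g) {
    p->seqs.push_back(as<std::string>(seqs[g]));
  }
  for (size_t g = 0; g < p->seqs.size(); ++g) {
    for_each_kmer(p->seqs[g], k, [&](uint64_t v, int32_t pos) {
      p->idx[v].push_back({static_cast<int32_t>(g), pos});
    });
  }
  return p;
}

// [[Rcpp::export]]
bool kmer_index_valid(SEXP ptr) {
  return TYPEOF(ptr) == EXTPTRSXP && R_ExternalPtrAddr(ptr) != nullptr;
}

// [[Rcpp::export]]
DataFrame kmer_index_lookup(SEXP ptr, std::string kmer) {
  KmerIndex* ki = get_index(ptr);
  if (static_cast<int>(kmer.size()) != ki->k) {
    stop("query length must equal index k");
  }
  std::vector<int> genome, pos;
  std::vector<std::string> strand;
  uint64_t fw;
  if (pack_kmer(kmer, &fw)) {
    std::string rc(kmer.size(), 'N');
    for (size_t j = 0; j < kmer.size(); ++j) {
      rc[j] = base_comp(kmer[kmer.size() - 1 - j]);
    }
    uint64_t rv;
    pack_kmer(rc, &rv);
    auto it = ki->idx.find(fw);
    if (it != ki->idx.end()) {
      for (auto& gp : it->second) {
        genome.push_back(gp.first + 1);
        pos.push_back(gp.second);
        strand.push_back("+");
      }
    }
    if (rv != fw) {
      it = ki->idx.find(rv);
      if (it != ki->idx.end()) {
        for (auto& gp : it->second) {
          genome.push_back(gp.first + 1);
          pos.push_back(gp.second);
          strand.push_back("-");
        }
      }
    }
  }
  return DataFrame::create(_["genome"] = genome, _["position"] = pos,
                           _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame map_reads_cpp(SEXP ptr, CharacterVector reads, double min_identity,
                        double min_cov) {
  KmerIndex* ki = get_index(ptr);
  const int k = ki->k;

  std::vector<int> o_read, o_genome, o_pos, o_alen, o_match;
  std::vector<int> o_strand;  // 0 = '+', 1 = '-'

  struct Best {
    int matches = -1;
    int alen = 0;
    int pos = 0;
    int strand = 0;
  };

  std::vector<std::pair<int32_t, int64_t>> diags;

  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    const int len = static_cast<int>(s.size());
    if (len < k) continue;
    std::string rc(len, 'N');
    for (int j = 0; j < len; ++j) rc[j] = base_comp(s[len - 1 - j]);

    std::map<int, Best> best;
    for (int st = 0; st < 2; ++st) {
      const std::string& q = (st == 0) ? s : rc;
      diags.clear();
      for_each_kmer(q, k, [&](uint64_t v, int32_t qpos) {
        auto it = ki->idx.find(v);
        if (it == ki->idx.end()) return;
        for (auto& gp : it->second) {
          diags.push_back({gp.first, static_cast<int64_t>(gp.second) - qpos});
        }
      });
      std::sort(diags.begin(), diags.end());
      diags.erase(std::unique(diags.begin(), diags.end()), diags.end());

      for (auto& gd : diags) {
        const std::string& G = ki->seqs[gd.first];
        const int64_t d = gd.second;
        const int lo = d < 0 ? static_cast<int>(-d) : 0;
        const int hi = static_cast<int>(
            std::min<int64_t>(len, static_cast<int64_t>(G.size()) - d));
        const int alen = hi - lo;
        if (alen < min_cov * len) continue;
        int m = 0;
        const char* gp = G.data() + d + lo;
        const char* qp = q.data() + lo;
        for (int j = 0; j < alen; ++j) {
          if (qp[j] == gp[j]) ++m;
        }
        if (static_cast<double>(m) / alen < min_identity) continue;
        const int pos = static_cast<int>(d + lo);
        Best& b = best[gd.first];
        const bool better =
            (m > b.matches) || (m == b.matches && alen < b.alen) ||
            (m == b.matches && alen == b.alen && pos < b.pos) ||
            (m == b.matches && alen == b.alen && pos == b.pos &&
             st < b.strand);
        if (better) {
          b.matches = m;
          b.alen = alen;
          b.pos = pos;
          b.strand = st;
        }
      }
    }
    for (auto& gb : best) {
      o_read.push_back(static_cast<int>(i) + 1);
      o_genome.push_back(gb.first + 1);
      o_pos.push_back(gb.second.pos);
      o_alen.push_back(gb.second.alen);
      o_match.push_back(gb.second.matches);
      o_strand.push_back(gb.second.strand);
    }
  }

  const R_xlen_t n = static_cast<R_xlen_t>(o_read.size());
  CharacterVector strand(n);
  for (R_xlen_t j = 0; j < n; ++j) strand[j] = o_strand[j] == 0 ? "+" : "-";
  return DataFrame::create(
      _["read"] = IntegerVector(o_read.begin(), o_read.end()),
      _["genome"] = IntegerVector(o_genome.begin(), o_genome.end()),
      _["pos"] = IntegerVector(o_pos.begin(), o_pos.end()),
      _["strand"] = strand,
      _["aligned_length"] = IntegerVector(o_alen.begin(), o_alen.end()),
      _["matches"] = IntegerVector(o_match.begin(), o_match.end()),
      _["stringsAsFactors"] = false);
}
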
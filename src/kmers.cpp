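#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

// 2-bit encoding A=0, C=1, G=2, T=3 preserves lexicographic order, so the
// canonical (lexicographically smaller of k-mer / reverse complement) form is
// the numerically smaller encoding. k <= 31 fits in 62 bits of a uint64_t.

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static std::string decode_kmer(uint64_t enc, int k) {
  static const char bases[] = "ACGT";
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = bases[enc & 3ULL];
    enc >>= 2;
  }
  return s;
}

// Enumerate canonical k-mers of one sequence into `out` (count per k-mer).
static void count_seq(const char* seq, size_t n, int k,
                      std::unordered_map<uint64_t, uint32_t>& out) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
    if (++run >= k) {
      uint64_t canon = fwd < rev ? fwd : rev;
      ++out[canon];
    }
  }
}

// [[Rcpp::export(name = ".cpp_count_kmers")]]
CharacterVector cpp_count_kmers(CharacterVector seqs, int k, int min_count) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  std::unordered_map<uint64_t, uint32_t> counts;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    count_seq(s, LENGTH(STRING_ELT(seqs, i)), k, counts);
  }
  std::vector<uint64_t> keep;
  keep.reserve(counts.size());
  for (const auto& kv : counts)
    if ((int)kv.second >= min_count) keep.push_back(kv.first);
  std::sort(keep.begin(), keep.end());
  CharacterVector res(keep.size());
  for (size_t i = 0; i < keep.size(); ++i)
    res[i] = decode_kmer(keep[i], k);
  return res;
}

// Accumulator of per-sex presence counts over samples, so read sets can be
// streamed one sample at a time without holding all panels in memory.
struct KmerAccumulator {
  int k;
  // value: (n female panels present, n male panels present)
  std::unordered_map<uint64_t, std::pair<uint16_t, uint16_t> > presence;
  int n_female = 0, n_male = 0;
};

// [[Rcpp::export(name = ".cpp_kmer_acc_new")]]
SEXP cpp_kmer_acc_new(int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  KmerAccumulator* acc = new KmerAccumulator();
  acc->k = k;
  XPtr<KmerAccumulator> ptr(acc, true);
  return ptr;
}

// [[Rcpp::export(name = ".cpp_kmer_acc_add")]]
void cpp_kmer_acc_add(SEXP accp, CharacterVector reads, int min_count,
                      bool is_female) {
  XPtr<KmerAccumulator> acc(accp);
  std::unordered_map<uint64_t, uint32_t> counts;
  counts.reserve(1 << 22);
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    count_seq(s, LENGTH(STRING_ELT(reads, i)), acc->k, counts);
  }
  for (const auto& kv : counts) {
    if ((int)kv.second < min_count) continue;
    auto& pr = acc->presence[kv.first];
    if (is_female) ++pr.first; else ++pr.second;
  }
  if (is_female) ++acc->n_female; else ++acc->n_male;
}

// [[Rcpp::export(name = ".cpp_kmer_acc_select")]]
CharacterVector cpp_kmer_acc_select(SEXP accp, int min_female, int max_male) {
  XPtr<KmerAccumulator> acc(accp);
  std::vector<uint64_t> keep;
  for (const auto& kv : acc->presence)
    if ((int)kv.second.first >= min_female && (int)kv.second.second <= max_male)
      keep.push_back(kv.first);
  std::sort(keep.begin(), keep.end());
  CharacterVector res(keep.size());
  for (size_t i = 0; i < keep.size(); ++i)
    res[i] = decode_kmer(keep[i], acc->k);
  return res;
}

// [[Rcpp::export(name = ".cpp_kmer_acc_counts")]]
IntegerVector cpp_kmer_acc_counts(SEXP accp) {
  XPtr<KmerAccumulator> acc(accp);
  return IntegerVector::create(_["n_female"] = acc->n_female,
                               _["n_male"] = acc->n_male,
                               _["n_kmers"] = (int)acc->presence.size());
}
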
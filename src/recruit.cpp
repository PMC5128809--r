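// k-mer index + gapless seed-and-extend mapper, plus sequence-simulation
// helpers. All randomness goes through R's RNG so results are reproducible
// under set.seed().
#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

namespace {

inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

inline char complement(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (std::string::iterator it = r.begin(); it != r.end(); ++it)
    *it = complement(*it);
  return r;
}

struct KmerIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  // kmer code -> packed (chrom << 40) | position (0-based, forward strand)
  std::unordered_map<uint64_t, std::vector<uint64_t> > table;
};

const uint64_t POS_MASK = (1ULL << 40) - 1;

// call f(code, pos) for every ACGT-only k-mer of s
template <typename F>
void for_each_kmer(const std::string& s, int k, F f) {
  if ((int)s.size() < k) return;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t code = 0;
  int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base2bit(s[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++run >= k) f(code, (long)(i + 1 - k));
  }
}

bool encode_kmer(const std::string& s, uint64_t& code) {
  code = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base2bit(s[i]);
    if (b < 0) return false;
    code = (code << 2) | (uint64_t)b;
  }
  return true;
}

int count_matches(const std::string& q, const std::string& ref, long start) {
  int m = 0;
  for (size_t i = 0; i < q.size(); ++i)
    if (q[i] == ref[start + i]) ++m;
  return m;
}

struct Best {
  bool found;
  int matches;
  long chrom, start;
  bool fwd;
  Best() : found(false), matches(-1), chrom(0), start(0), fwd(true) {}
};

// best gapless full-length placement of read among all seeded candidate loci;
// ties broken by (chrom index, start, forward strand first)
Best best_locus(const std::string& fwd, const std::string& rc,
                const KmerIndex& idx) {
  const long len = (long)fwd.size();
  std::vector<uint64_t> cands;  // (chrom << 41) | (start << 1) | strand(rc=1)
  for (int strand = 0; strand < 2; ++strand) {
    const std::string& q = strand ? rc : fwd;
    for_each_kmer(q, idx.k, [&](uint64_t code, long qpos) {
      std::unordered_map<uint64_t, std::vector<uint64_t> >::const_iterator it =
          idx.table.find(code);
      if (it == idx.table.end()) return;
      for (size_t j = 0; j < it->second.size(); ++j) {
        long chrom = (long)(it->second[j] >> 40);
        long pos = (long)(it->second[j] & POS_MASK);
        long start = pos - qpos;
        if (start < 0) continue;
        if (start + len > (long)idx.seqs[chrom].size()) continue;
        cands.push_back(((uint64_t)chrom << 41) | ((uint64_t)start << 1) |
                        (uint64_t)strand);
      }
    });
  }
  std::sort(cands.begin(), cands.end());
  cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
  Best best;
  for (size_t i = 0; i < cands.size(); ++i) {
    long chrom = (long)(cands[i] >> 41);
    long start = (long)((cands[i] >> 1) & POS_MASK);
    bool is_rc = (cands[i] & 1ULL) != 0;
    const std::string& q = is_rc ? rc : fwd;
    int m = count_matches(q, idx.seqs[chrom], start);
    // candidates iterate in (chrom, start, fwd-before-rc) order, so strict
    // '>' implements the deterministic tie-break
    if (m > best.matches) {
      best.found = true;
      best.matches = m;
      best.chrom = chrom;
      best.start = start;
      best.fwd = !is_rc;
    }
  }
  return best;
}

}  // namespace

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector names, CharacterVector seqs, int k) {
  if (k < 11 || k > 31) stop("k must be between 11 and 31");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() < k) {
      delete idx;
      stop("k (%d) exceeds the length of chromosome '%s'", k,
           as<std::string>(names[i]).c_str());
    }
    idx->names.push_back(as<std::string>(names[i]));
    idx->seqs.push_back(s);
    long chrom = i;
    for_each_kmer(s, k, [&](uint64_t code, long pos) {
      idx->table[code].push_back(((uint64_t)chrom << 40) | (uint64_t)pos);
    });
  }
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_index_stats(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  size_t npos = 0;
  for (std::unordered_map<uint64_t, std::vector<uint64_t> >::const_iterator
           it = idx->table.begin();
       it != idx->table.end(); ++it)
    npos += it->second.size();
  return List::create(_["k"] = idx->k,
                      _["n_kmers"] = (double)idx->table.size(),
                      _["n_positions"] = (double)npos);
}

// positions at which `kmer` occurs: strand "+" means the forward genome
// sequence equals the k-mer at that position, "-" means its reverse
// complement does
// [[Rcpp::export]]
DataFrame cpp_lookup(SEXP xp, std::string kmer) {
  XPtr<KmerIndex> idx(xp);
  if ((int)kmer.size() != idx->k)
    stop("query length (%d) differs from index k (%d)", (int)kmer.size(),
         idx->k);
  std::vector<int> chrom;
  std::vector<double> pos;
  std::vector<std::string> strand;
  uint64_t code;
  if (encode_kmer(kmer, code)) {
    std::unordered_map<uint64_t, std::vector<uint64_t> >::const_iterator it =
        idx->table.find(code);
    if (it != idx->table.end())
      for (size_t j = 0; j < it->second.size(); ++j) {
        chrom.push_back((int)(it->second[j] >> 40) + 1);
        pos.push_back((double)(it->second[j] & POS_MASK));
        strand.push_back("+");
      }
    uint64_t rc_code;
    std::string rc = revcomp(kmer);
    if (encode_kmer(rc, rc_code) && rc_code != code) {
      it = idx->table.find(rc_code);
      if (it != idx->table.end())
        for (size_t j = 0; j < it->second.size(); ++j) {
          chrom.push_back((int)(it->second[j] >> 40) + 1);
          pos.push_back((double)(it->second[j] & POS_MASK));
          strand.push_back("-");
        }
    }
  }
  return DataFrame::create(_["chrom"] = chrom, _["pos"] = pos,
                           _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
CharacterVector cpp_index_chroms(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  return wrap(idx->names);
}

// best gapless placement of each read on each of (up to) two genomes
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, SEXP xpa, SEXP xpb) {
  XPtr<KmerIndex> ia(xpa);
  KmerIndex* ib = NULL;
  if (!Rf_isNull(xpb)) {
    XPtr<KmerIndex> tmp(xpb);
    ib = tmp.get();
  }
  int n = reads.size();
  IntegerVector a_chrom(n, NA_INTEGER), b_chrom(n, NA_INTEGER);
  NumericVector a_start(n, NA_REAL), b_start(n, NA_REAL);
  IntegerVector a_matches(n, NA_INTEGER), b_matches(n, NA_INTEGER);
  NumericVector a_identity(n, NA_REAL), b_identity(n, NA_REAL);
  CharacterVector a_strand(n, NA_STRING), b_strand(n, NA_STRING);
  IntegerVector rlen(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    int len = (int)fwd.size();
    rlen[i] = len;
    if (len < ia->k) continue;
    std::string rc = revcomp(fwd);
    Best ba = best_locus(fwd, rc, *ia);
    if (ba.found) {
      a_chrom[i] = (int)ba.chrom + 1;
      a_start[i] = (double)ba.start;
      a_matches[i] = ba.matches;
      a_identity[i] = 100.0 * ba.matches / len;
      a_strand[i] = ba.fwd ? "+" : "-";
    }
    if (ib != NULL) {
      Best bb = best_locus(fwd, rc, *ib);
      if (bb.found) {
        b_chrom[i] = (int)bb.chrom + 1;
        b_start[i] = (double)bb.start;
        b_matches[i] = bb.matches;
        b_identity[i] = 100.0 * bb.matches / len;
        b_strand[i] = bb.fwd ? "+" : "-";
      }
    }
  }
  return DataFrame::create(
      _["read_length"] = rlen, _["a_chrom"] = a_chrom, _["a_start"] = a_start,
      _["a_strand"] = a_strand, _["a_matches"] = a_matches,
      _["a_identity"] = a_identity, _["b_chrom"] = b_chrom,
      _["b_start"] = b_start, _["b_strand"] = b_strand,
      _["b_matches"] = b_matches, _["b_identity"] = b_identity,
      _["stringsAsFactors"] = false);
}

// random DNA with a given GC fraction (G/C and A/T equiprobable within class)
// [[Rcpp::export]]
std::string cpp_random_dna(int n, double gc) {
  std::string s(n, 'A');
  for (int i = 0; i < n; ++i) {
    double u = unif_rand();
    if (u < gc / 2) s[i] = 'G';
    else if (u < gc) s[i] = 'C';
    else if (u < gc + (1 - gc) / 2) s[i] = 'A';
    else s[i] = 'T';
  }
  return s;
}

// i.i.d. per-site substitution to a different base; rate can be overridden on
// 0-based half-open intervals (last interval wins on overlap)
// [[Rcpp::export]]
std::string cpp_mutate_ranges(std::string seq, double default_rate,
                              IntegerVector starts, IntegerVector ends,
                              NumericVector rates) {
  const char* bases = "ACGT";
  std::vector<double> rate(seq.size(), default_rate);
  for (int j = 0; j < starts.size(); ++j)
    for (int p = starts[j]; p < ends[j]; ++p)
      if (p >= 0 && p < (int)seq.size()) rate[p] = rates[j];
  for (size_t i = 0; i < seq.size(); ++i) {
    if (rate[i] <= 0) continue;
    int b = base2bit(seq[i]);
    if (b < 0) continue;
    if (unif_rand() < rate[i]) {
      int nb = (b + 1 + (int)(unif_rand() * 3)) & 3;
      seq[i] = bases[nb];
    }
  }
  return seq;
}

// [[Rcpp::export]]
std::string cpp_mutate(std::string seq, double rate) {
  return cpp_mutate_ranges(seq, rate, IntegerVector(0), IntegerVector(0),
                           NumericVector(0));
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i)
    out[i] = revcomp(as<std::string>(x[i]));
  return out;
}
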
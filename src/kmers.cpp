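#include <Rcpp.h>
#include <unordered_map>
#include <string>
using namespace Rcpp;

// k-mers occurring in exactly one gene across the concatenated gene set.
// Returns a list with the unique k-mers and the (1-based) index of the
// gene each belongs to. K-mers seen in two or more genes are discarded.
// [[Rcpp::export]]
List unique_kmer_index(CharacterVector seqs, int k) {
  std::unordered_map<std::string, int> map; // kmer -> gene idx, -1 = shared
  for (int g = 0; g < seqs.size(); ++g) {
    std::string s = as<std::string>(seqs[g]);
    if ((int)s.size() < k) continue;
    for (size_t i = 0; i + k <= s.size(); ++i) {
      std::string km = s.substr(i, k);
      auto it = map.find(km);
      if (it == map.end()) {
        map[km] = g + 1;
      } else if (it->second != g + 1) {
        it->second = -1;
      }
    }
  }
  size_t n = 0;
  for (auto &kv : map) if (kv.second > 0) ++n;
  CharacterVector kmers(n);
  IntegerVector gene(n);
  size_t j = 0;
  for (auto &kv : map) {
    if (kv.second > 0) {
      kmers[j] = kv.first;
      gene[j] = kv.second;
      ++j;
    }
  }
  return List::create(_["kmer"] = kmers, _["gene"] = gene);
}

// Assign each read by scanning all its k-mers against the unique-k-mer
// index: exactly one gene hit -> that gene's index; hits to >= 2 genes ->
// -1 (multimapper); no hits -> 0.
// [[Rcpp::export]]
IntegerVector assign_reads_kmer(CharacterVector reads, CharacterVector kmers,
                                IntegerVector gene, int k) {
  std::unordered_map<std::string, int> map;
  map.reserve(kmers.size() * 2);
  for (int i = 0; i < kmers.size(); ++i)
    map[as<std::string>(kmers[i])] = gene[i];
  IntegerVector out(reads.size());
  for (int r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    int hit = 0;
    bool multi = false;
    if ((int)s.size() >= k) {
      for (size_t i = 0; i + k <= s.size(); ++i) {
        auto it = map.find(s.substr(i, k));
        if (it != map.end()) {
          if (hit == 0) {
            hit = it->second;
          } else if (hit != it->second) {
            multi = true;
            break;
          }
        }
      }
    }
    out[r] = multi ? -1 : hit;
  }
  return out;
}

// Greedy count-descending UMI absorption within one (gene, barcode)
// group: UMIs sorted by descending read count (ties lexicographic) are
// accepted unless within hamming distance <= max_dist of an already
// accepted UMI. Input must be pre-sorted; returns the number accepted.
// [[Rcpp::export]]
int collapse_umis_sorted(CharacterVector umis, int max_dist) {
  std::vector<std::string> acc;
  int n = umis.size();
  for (int i = 0; i < n; ++i) {
    std::string u = as<std::string>(umis[i]);
    bool absorbed = false;
    for (auto &a : acc) {
      int d = 0;
      for (size_t p = 0; p < u.size(); ++p) {
        if (u[p] != a[p] && ++d > max_dist) break;
      }
      if (d <= max_dist) { absorbed = true; break; }
    }
    if (!absorbed) acc.push_back(u);
  }
  return (int)acc.size();
}
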
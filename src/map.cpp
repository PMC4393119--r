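#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// ungapped placement of full-length reads on contigs, all positions with
// Hamming distance <= mm_max reported.

// [[Rcpp::export]]
DataFrame map_reads_cpp(CharacterVector reads, CharacterVector contigs,
                        int mm_max) {
  std::vector<int> r_idx, c_idx, starts, mms;
  std::vector<std::string> ctg(contigs.size());
  for (int c = 0; c < contigs.size(); ++c) ctg[c] = as<std::string>(contigs[c]);

  for (int r = 0; r < reads.size(); ++r) {
    std::string rd = as<std::string>(reads[r]);
    int L = rd.size();
    for (int c = 0; c < (int)ctg.size(); ++c) {
      const std::string& s = ctg[c];
      int n = s.size();
      for (int p = 0; p + L <= n; ++p) {
        int mm = 0;
        for (int k = 0; k < L; ++k) {
          if (rd[k] != s[p + k] && ++mm > mm_max) break;
        }
        if (mm <= mm_max) {
          r_idx.push_back(r + 1);
          c_idx.push_back(c + 1);
          starts.push_back(p);
          mms.push_back(mm);
        }
      }
    }
  }
  return DataFrame::create(_["read"] = r_idx, _["contig"] = c_idx,
                           _["start"] = starts, _["mismatches"] = mms);
}
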
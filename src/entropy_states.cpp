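#include <Rcpp.h>
#include <unordered_map>
#include <cstdio>
using namespace Rcpp;

// Per-step pattern keys for coarse-grained spike rasters.  Spikes arrive
// as (step, channel) pairs, 1-based, ordered by step; the key for a step
// is the sorted "channel:count" list, "" for silent steps.
// [[Rcpp::export]]
CharacterVector pattern_keys_cpp(IntegerVector step, IntegerVector channel,
                                 int n_steps) {
  CharacterVector keys(n_steps, "");
  const int ns = step.size();
  std::string buf;
  char item[32];
  int i = 0;
  while (i < ns) {
    int t = step[i];
    int j = i;
    while (j < ns && step[j] == t) ++j;
    std::vector<int> ch(channel.begin() + i, channel.begin() + j);
    std::sort(ch.begin(), ch.end());
    buf.clear();
    size_t k = 0;
    while (k < ch.size()) {
      size_t l = k;
      while (l < ch.size() && ch[l] == ch[k]) ++l;
      std::snprintf(item, sizeof(item), "%d:%d", ch[k], (int)(l - k));
      if (!buf.empty()) buf.push_back(',');
      buf += item;
      k = l;
    }
    if (t >= 1 && t <= n_steps) keys[t - 1] = buf;
    i = j;
  }
  return keys;
}
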
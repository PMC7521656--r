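#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Hamming distance with early exit once `limit` is exceeded.
// Strings must be compared over their common (equal) length by the caller.
static inline int ham_limited(const char *a, const char *b, int n, int limit) {
  int d = 0;
  for (int i = 0; i < n; ++i) {
    if (a[i] != b[i]) {
      if (++d > limit) return d;
    }
  }
  return d;
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  case 'a': return 't';
  case 'c': return 'g';
  case 'g': return 'c';
  case 't': return 'a';
  case 'N': return 'N';
  case 'n': return 'n';
  default:  return 'N';
  }
}

static std::string revcomp_one(const std::string &s) {
  std::string out(s.rbegin(), s.rend());
  for (size_t i = 0; i < out.size(); ++i) out[i] = comp_base(out[i]);
  return out;
}

//' Reverse complement of DNA strings
//'
//' @param x character vector of DNA sequences (A/C/G/T; other symbols map
//'   to N).
//' @return character vector of the same length with each element
//'   reverse-complemented.
//' @export
// [[Rcpp::export]]
CharacterVector revcomp(CharacterVector x) {
  R_xlen_t n = x.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_STRING; continue; }
    out[i] = revcomp_one(as<std::string>(x[i]));
  }
  out.attr("names") = x.attr("names");
  return out;
}

//' Hamming distance between two equal-length strings
//'
//' @param a,b single strings of equal length.
//' @return integer mismatch count.
//' @export
// [[Rcpp::export]]
int hamming(std::string a, std::string b) {
  if (a.size() != b.size())
    stop("hamming() requires equal-length strings (got %d and %d)",
         (int)a.size(), (int)b.size());
  return ham_limited(a.c_str(), b.c_str(), a.size(), a.size());
}

// All 0-based start positions in `text` where `pattern` matches with
// Hamming distance <= max_mm. Returns an integer matrix-like list:
// positions and their mismatch counts.
// [[Rcpp::export]]
List find_matches_cpp(std::string text, std::string pattern, int max_mm) {
  int n = text.size(), m = pattern.size();
  std::vector<int> pos, mm;
  if (m > 0 && n >= m) {
    const char *t = text.c_str(), *p = pattern.c_str();
    for (int i = 0; i <= n - m; ++i) {
      int d = ham_limited(t + i, p, m, max_mm);
      if (d <= max_mm) { pos.push_back(i); mm.push_back(d); }
    }
  }
  return List::create(_["pos"] = wrap(pos), _["mm"] = wrap(mm));
}

// Locate adapter + k random bases + anchor at the 5' end of each read,
// trying both orientations; return the remainder after the anchor.
// reasons: "" (accepted), "no_adapter", "no_anchor", "empty_remainder".
// [[Rcpp::export]]
List trim_reads_cpp(CharacterVector reads, std::string adapter,
                    std::string anchor, int max_mm,
                    int prefix_min, int prefix_max) {
  R_xlen_t n = reads.size();
  int al = adapter.size(), kl = anchor.size();
  CharacterVector trimmed(n), reason(n), orient(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    std::string rev = revcomp_one(fwd);
    bool adapter_seen = false, done = false;
    for (int o = 0; o < 2 && !done; ++o) {
      const std::string &s = (o == 0) ? fwd : rev;
      int len = s.size();
      if (len < al) continue;
      if (ham_limited(s.c_str(), adapter.c_str(), al, max_mm) > max_mm)
        continue;
      adapter_seen = true;
      for (int k = prefix_min; k <= prefix_max && !done; ++k) {
        int a0 = al + k;
        if (a0 + kl > len) break;
        if (ham_limited(s.c_str() + a0, anchor.c_str(), kl, max_mm) <= max_mm) {
          std::string rest = s.substr(a0 + kl);
          if (rest.empty()) {
            trimmed[i] = NA_STRING; reason[i] = "empty_remainder";
          } else {
            trimmed[i] = rest; reason[i] = "";
          }
          orient[i] = (o == 0) ? "+" : "-";
          done = true;
        }
      }
    }
    if (!done) {
      trimmed[i] = NA_STRING;
      reason[i] = adapter_seen ? "no_anchor" : "no_adapter";
      orient[i] = NA_STRING;
    }
  }
  return List::create(_["trimmed"] = trimmed, _["reason"] = reason,
                      _["orient"] = orient);
}

// Greedy repeat-spacer scan of a trimmed read. The read must begin at the
// first repeat; inter-repeat segments up to the endogenous next-spacer
// prefix (or read end) are returned leader-proximal first.
// status: "expanded", "unexpanded", "no_repeat_start", "short_segment",
//         "no_terminal_anchor".
// [[Rcpp::export]]
List scan_array_cpp(CharacterVector trimmed, std::string rep, int rep_mm,
                    std::string next_prefix, int anchor_mm,
                    int min_spacer, int max_spacer) {
  R_xlen_t n = trimmed.size();
  int rl = rep.size(), pl = next_prefix.size();
  CharacterVector status(n);
  List spacers(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(trimmed[i])) {
      status[i] = NA_STRING; spacers[i] = CharacterVector(0); continue;
    }
    std::string t = as<std::string>(trimmed[i]);
    int len = t.size();
    std::vector<std::string> segs;
    if (len < rl ||
        ham_limited(t.c_str(), rep.c_str(), rl, rep_mm) > rep_mm) {
      status[i] = "no_repeat_start"; spacers[i] = CharacterVector(0);
      continue;
    }
    int pos = rl;
    std::string st = "";
    while (st.empty()) {
      // endogenous array reached?
      if (len - pos >= pl &&
          ham_limited(t.c_str() + pos, next_prefix.c_str(), pl,
                      anchor_mm) <= anchor_mm) {
        st = segs.empty() ? "unexpanded" : "expanded";
        break;
      }
      // next repeat occurrence
      int q = -1;
      for (int cand = pos + min_spacer; cand <= len - rl; ++cand) {
        if (ham_limited(t.c_str() + cand, rep.c_str(), rl, rep_mm) <= rep_mm) {
          q = cand; break;
        }
      }
      if (q >= 0) {
        segs.push_back(t.substr(pos, q - pos));
        pos = q + rl;
      } else {
        // read end without the endogenous anchor: a trailing segment of
        // plausible spacer length is kept (truncated read), else reject
        int tail = len - pos;
        if (tail >= min_spacer && tail <= max_spacer) {
          segs.push_back(t.substr(pos));
          st = "expanded";
        } else if (tail < min_spacer) {
          st = "short_segment";
        } else {
          st = "no_terminal_anchor";
        }
      }
    }
    if (st == "short_segment" || st == "no_terminal_anchor")
      segs.clear();
    status[i] = st;
    spacers[i] = wrap(segs);
  }
  return List::create(_["status"] = status, _["spacers"] = spacers);
}
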
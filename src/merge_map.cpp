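#include <Rcpp.h>
using namespace Rcpp;

// Overlap-merge of read pairs. r2rc is the reverse complement of R2.
// For each pair, scan overlap lengths from the longest possible down to
// min_overlap and accept the first whose mismatch rate is within
// max_mm_rate; disagreeing overlap bases are resolved in favor of R1.
// [[Rcpp::export(name = ".merge_pairs_cpp")]]
List merge_pairs_cpp(CharacterVector r1, CharacterVector r2rc,
                     int min_overlap, double max_mm_rate) {
  int n = r1.size();
  if (r2rc.size() != n) stop("r1 and r2 lengths differ");
  CharacterVector merged(n);
  IntegerVector overlap(n), mm(n);
  LogicalVector ok(n);
  for (int i = 0; i < n; ++i) {
    const char *a = CHAR(STRING_ELT(r1, i));
    const char *b = CHAR(STRING_ELT(r2rc, i));
    int n1 = LENGTH(STRING_ELT(r1, i));
    int n2 = LENGTH(STRING_ELT(r2rc, i));
    int best_o = -1, best_mm = 0;
    int omax = n1 < n2 ? n1 : n2;
    for (int o = omax; o >= min_overlap && o >= 1; --o) {
      int lim = (int)std::floor(max_mm_rate * o + 1e-9);
      int m = 0;
      const char *sa = a + (n1 - o);
      bool pass = true;
      for (int j = 0; j < o; ++j) {
        if (sa[j] != b[j]) {
          if (++m > lim) { pass = false; break; }
        }
      }
      if (pass) { best_o = o; best_mm = m; break; }
    }
    if (best_o < 0) {
      merged[i] = NA_STRING;
      overlap[i] = NA_INTEGER;
      mm[i] = NA_INTEGER;
      ok[i] = false;
    } else {
      std::string out(a, n1);
      out.append(b + best_o, n2 - best_o);
      merged[i] = out;
      overlap[i] = best_o;
      mm[i] = best_mm;
      ok[i] = true;
    }
  }
  return List::create(_["merged"] = merged, _["overlap"] = overlap,
                      _["mismatches"] = mm, _["ok"] = ok);
}

// Best reference by Hamming distance for each read (equal-length,
// end-gap-free, co-linear comparison). References whose length differs
// from the read are skipped (length_mismatch flags a read no reference
// matched in length). Early exit once a comparison exceeds the current
// best. Returns the 1-based best index, its mismatch count, and the
// number of equal-best references (ties => ambiguous).
// [[Rcpp::export(name = ".map_hamming_cpp")]]
List map_hamming_cpp(CharacterVector reads, CharacterVector refs) {
  int n = reads.size(), m = refs.size();
  if (m == 0) stop("empty reference set");
  IntegerVector best_idx(n), best_mm(n), n_best(n);
  LogicalVector len_mismatch(n);
  std::vector<const char*> rp(m);
  std::vector<int> rl(m);
  for (int j = 0; j < m; ++j) {
    rp[j] = CHAR(STRING_ELT(refs, j));
    rl[j] = LENGTH(STRING_ELT(refs, j));
  }
  for (int i = 0; i < n; ++i) {
    const char *a = CHAR(STRING_ELT(reads, i));
    int na = LENGTH(STRING_ELT(reads, i));
    int best = INT_MAX, bidx = -1, ties = 0;
    bool any_len = false;
    for (int j = 0; j < m; ++j) {
      if (rl[j] != na) continue;
      any_len = true;
      const char *b = rp[j];
      int mm = 0;
      for (int k = 0; k < na; ++k) {
        if (a[k] != b[k]) {
          if (++mm > best) break;
        }
      }
      if (mm < best) { best = mm; bidx = j; ties = 1; }
      else if (mm == best) ++ties;
    }
    if (!any_len) {
      best_idx[i] = NA_INTEGER; best_mm[i] = NA_INTEGER;
      n_best[i] = NA_INTEGER; len_mismatch[i] = true;
    } else {
      best_idx[i] = bidx + 1; best_mm[i] = best;
      n_best[i] = ties; len_mismatch[i] = false;
    }
  }
  return List::create(_["best_idx"] = best_idx, _["best_mm"] = best_mm,
                      _["n_best"] = n_best,
                      _["length_mismatch"] = len_mismatch);
}

// Per-position mismatch tally of equal-length reads against a reference.
// Returns the count of reads substituted at each position, plus each
// read's total mismatch count.
// [[Rcpp::export(name = ".position_mismatch_cpp")]]
List position_mismatch_cpp(CharacterVector reads, std::string ref) {
  int n = reads.size();
  int L = ref.size();
  IntegerVector per_read(n);
  IntegerVector per_pos(L);
  for (int i = 0; i < n; ++i) {
    const char *a = CHAR(STRING_ELT(reads, i));
    int na = LENGTH(STRING_ELT(reads, i));
    if (na != L) { per_read[i] = NA_INTEGER; continue; }
    int mm = 0;
    for (int k = 0; k < L; ++k) {
      if (a[k] != ref[k]) { ++mm; ++per_pos[k]; }
    }
    per_read[i] = mm;
  }
  return List::create(_["per_read"] = per_read, _["per_pos"] = per_pos);
}
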
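#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Glocal alignment: the subject (germline segment) is aligned end-to-end,
// the pattern (read) locally -- free pattern overhangs on both sides.
// Linear gap penalty. Traceback prefers diagonal, then subject-gap, so the
// alignment is deterministic. Returns, per read: score, matches, aligned
// columns, 1-based pattern start/end of the aligned region, and the 0-based
// pattern offset of the subject anchor codon (-1 when the codon is not
// covered by three consecutive diagonal columns).
// [[Rcpp::export(name = ".glocal_align_batch")]]
DataFrame glocal_align_batch(CharacterVector reads, std::string subject,
                             double match, double mismatch, double gap,
                             int anchor0) {
  const int m = subject.size();
  const int nreads = reads.size();
  NumericVector score(nreads);
  IntegerVector matches(nreads), cols(nreads), p_start(nreads), p_end(nreads),
      anchor_read(nreads);

  for (int r = 0; r < nreads; ++r) {
    std::string pat = as<std::string>(reads[r]);
    const int n = pat.size();
    // H has (m+1) rows, (n+1) cols
    std::vector<double> H((m + 1) * (n + 1));
    for (int i = 0; i <= n; ++i) H[i] = 0.0;               // free pattern start
    for (int j = 1; j <= m; ++j) H[j * (n + 1)] = -gap * j; // subject consumed
    for (int j = 1; j <= m; ++j) {
      const char b = subject[j - 1];
      double *row = &H[j * (n + 1)], *prev = &H[(j - 1) * (n + 1)];
      for (int i = 1; i <= n; ++i) {
        const double s = (pat[i - 1] == b && b != 'N' && pat[i - 1] != 'N')
                             ? match : mismatch;
        double best = prev[i - 1] + s;        // diagonal
        if (prev[i] - gap > best) best = prev[i] - gap;  // gap in pattern
        if (row[i - 1] - gap > best) best = row[i - 1] - gap; // gap in subject
        row[i] = best;
      }
    }
    // best end column in last row
    int iend = 0;
    double bestsc = H[m * (n + 1)];
    for (int i = 1; i <= n; ++i)
      if (H[m * (n + 1) + i] > bestsc) { bestsc = H[m * (n + 1) + i]; iend = i; }

    // traceback
    int i = iend, j = m, nmatch = 0, ncols = 0;
    std::vector<int> patpos(m + 1, -1); // subject pos (1-based) -> pattern pos
    while (j > 0) {
      const double cur = H[j * (n + 1) + i];
      const char b = subject[j - 1];
      if (i > 0) {
        const double s = (pat[i - 1] == b && b != 'N' && pat[i - 1] != 'N')
                             ? match : mismatch;
        if (cur == H[(j - 1) * (n + 1) + (i - 1)] + s) {
          patpos[j] = i;
          if (pat[i - 1] == b) ++nmatch;
          --i; --j; ++ncols;
          continue;
        }
      }
      if (cur == H[(j - 1) * (n + 1) + i] - gap) { --j; ++ncols; continue; }
      // gap in subject
      --i; ++ncols;
    }
    const int istart = i + 1;
    score[r] = bestsc;
    matches[r] = nmatch;
    cols[r] = ncols;
    p_start[r] = istart;
    p_end[r] = iend;
    int ar = -1;
    if (anchor0 >= 0 && anchor0 + 3 <= m) {
      const int a = patpos[anchor0 + 1], b2 = patpos[anchor0 + 2],
                c = patpos[anchor0 + 3];
      if (a > 0 && b2 == a + 1 && c == a + 2) ar = a - 1; // 0-based
    }
    anchor_read[r] = ar;
  }
  return DataFrame::create(_["score"] = score, _["matches"] = matches,
                           _["cols"] = cols, _["p_start"] = p_start,
                           _["p_end"] = p_end, _["anchor_read"] = anchor_read);
}
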
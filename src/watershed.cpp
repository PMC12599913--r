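#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Neighborhood offsets. Images are R matrices (column-major); we index as
// idx = r + c * nrow throughout.
static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DR4[4] = {-1, 1, 0, 0};
static const int DC4[4] = {0, 0, -1, 1};

// Connected-component labeling of a binary mask. Labels are assigned in
// column-major scan order, so the result is deterministic and contiguous
// (1..K). connectivity must be 4 or 8.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity = 8) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  const int nnb = connectivity;
  const int *dr = (connectivity == 8) ? DR8 : DR4;
  const int *dc = (connectivity == 8) ? DC8 : DC4;
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % nr, pc = p / nr;
        for (int k = 0; k < nnb; ++k) {
          int qr = pr + dr[k], qc = pc + dc[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (mask(qr, qc) && lab(qr, qc) == 0) {
            lab(qr, qc) = next;
            stack.push_back(qr + qc * nr);
          }
        }
      }
    }
  }
  return lab;
}

struct QEntry {
  double elev;
  long long ord;   // insertion order: FIFO tie-break makes flooding deterministic
  int idx;
};
struct QCompare {
  bool operator()(const QEntry &a, const QEntry &b) const {
    if (a.elev != b.elev) return a.elev > b.elev;
    return a.ord > b.ord;
  }
};

// Watershed by flooding (Meyer-style) restricted to a foreground mask.
//
// Seeds are the regional minima of `elev` within the mask: connected
// (8-connected) plateaus of constant elevation with no lower mask neighbor.
// Each plateau becomes one seed label. Remaining mask pixels are flooded in
// order of increasing elevation; a pixel whose already-labeled neighbors
// carry more than one label becomes a ridge pixel and stays 0 in the output
// (ridges separate basins, as in labeling watershed lines with 0).
// [[Rcpp::export(name = ".cpp_watershed")]]
IntegerMatrix cpp_watershed(NumericMatrix elev, LogicalMatrix mask) {
  const int nr = elev.nrow(), nc = elev.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("elevation and mask dimensions differ");
  const int n = nr * nc;
  IntegerMatrix lab(nr, nc);        // 0 unlabeled, >0 basin, -1 ridge
  std::vector<char> seen(n, 0), inq(n, 0);
  std::vector<int> plateau;
  int nlab = 0;

  // --- regional minima (plateau-aware) ---
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int p0 = r + c * nr;
      if (!mask(r, c) || seen[p0]) continue;
      double v = elev(r, c);
      bool is_min = true;
      plateau.clear();
      plateau.push_back(p0);
      seen[p0] = 1;
      for (size_t i = 0; i < plateau.size(); ++i) {
        int p = plateau[i];
        int pr = p % nr, pc = p / nr;
        for (int k = 0; k < 8; ++k) {
          int qr = pr + DR8[k], qc = pc + DC8[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (!mask(qr, qc)) continue;
          double w = elev(qr, qc);
          if (w < v) {
            is_min = false;
          } else if (w == v) {
            int q = qr + qc * nr;
            if (!seen[q]) { seen[q] = 1; plateau.push_back(q); }
          }
        }
      }
      if (is_min) {
        ++nlab;
        for (size_t i = 0; i < plateau.size(); ++i)
          lab[plateau[i]] = nlab;
      }
    }
  }

  // --- flood ---
  std::priority_queue<QEntry, std::vector<QEntry>, QCompare> pq;
  long long ord = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (lab(r, c) <= 0) continue;
      for (int k = 0; k < 8; ++k) {
        int qr = r + DR8[k], qc = c + DC8[k];
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        int q = qr + qc * nr;
        if (mask(qr, qc) && lab[q] == 0 && !inq[q]) {
          inq[q] = 1;
          pq.push(QEntry{elev(qr, qc), ord++, q});
        }
      }
    }
  }
  while (!pq.empty()) {
    QEntry e = pq.top(); pq.pop();
    int p = e.idx;
    int pr = p % nr, pc = p / nr;
    int first = 0;
    bool conflict = false;
    for (int k = 0; k < 8; ++k) {
      int qr = pr + DR8[k], qc = pc + DC8[k];
      if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
      int l = lab(qr, qc);
      if (l > 0) {
        if (first == 0) first = l;
        else if (l != first) { conflict = true; break; }
      }
    }
    if (conflict || first == 0) {
      lab[p] = -1;  // ridge (or unreachable pocket walled off by ridges)
    } else {
      lab[p] = first;
      for (int k = 0; k < 8; ++k) {
        int qr = pr + DR8[k], qc = pc + DC8[k];
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        int q = qr + qc * nr;
        if (mask(qr, qc) && lab[q] == 0 && !inq[q]) {
          inq[q] = 1;
          pq.push(QEntry{elev(qr, qc), ord++, q});
        }
      }
    }
  }

  for (int i = 0; i < n; ++i)
    if (lab[i] < 0) lab[i] = 0;
  return lab;
}
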
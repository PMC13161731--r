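#include <Rcpp.h>
using namespace Rcpp;

// Two-pass connected-component labeling with union-find.
// Labels are assigned 1..K in raster-scan (column-major) first-touch order,
// so output is deterministic for a given input.

static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(LogicalMatrix fg, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = fg.nrow(), nc = fg.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0); // provisional label 0 unused

  // first pass: column-major scan, look at already-visited neighbours
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!fg(i, j)) continue;
      int best = 0;
      int neigh[4];
      int nn = 0;
      if (i > 0 && fg(i - 1, j)) neigh[nn++] = lab(i - 1, j);
      if (j > 0 && fg(i, j - 1)) neigh[nn++] = lab(i, j - 1);
      if (connectivity == 8) {
        if (i > 0 && j > 0 && fg(i - 1, j - 1)) neigh[nn++] = lab(i - 1, j - 1);
        if (i < nr - 1 && j > 0 && fg(i + 1, j - 1)) neigh[nn++] = lab(i + 1, j - 1);
      }
      for (int k = 0; k < nn; ++k)
        if (best == 0 || neigh[k] < best) best = neigh[k];
      if (best == 0) {
        int fresh = (int) parent.size();
        parent.push_back(fresh);
        lab(i, j) = fresh;
      } else {
        lab(i, j) = best;
        for (int k = 0; k < nn; ++k) uf_union(parent, best, neigh[k]);
      }
    }
  }

  // second pass: resolve roots, relabel to 1..K in first-touch order
  std::vector<int> remap(parent.size(), 0);
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      int r = uf_find(parent, l);
      if (remap[r] == 0) remap[r] = ++next;
      lab(i, j) = remap[r];
    }
  }
  return lab;
}
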
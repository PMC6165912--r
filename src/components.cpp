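// Connected-component labelling of 3-D binary masks (BFS flood fill).

#include <Rcpp.h>
#include <queue>

using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int X = dim[0], Y = dim[1], Z = dim[2];
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  IntegerVector lab((R_xlen_t)X * Y * Z);
  lab.attr("dim") = dim;

  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (man == 0) continue;
        if (connectivity == 6 && man != 1) continue;
        nb.push_back({dx, dy, dz});
      }

  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < lab.size(); ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int x = (int)(v % X), y = (int)((v / X) % Y), z = (int)(v / ((R_xlen_t)X * Y));
      for (auto& d : nb) {
        int nx = x + d[0], ny = y + d[1], nz = z + d[2];
        if (nx < 0 || ny < 0 || nz < 0 || nx >= X || ny >= Y || nz >= Z)
          continue;
        R_xlen_t u = nx + (R_xlen_t)X * (ny + (R_xlen_t)Y * nz);
        if (mask[u] && lab[u] == 0) { lab[u] = next; q.push(u); }
      }
    }
  }
  return lab;
}
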
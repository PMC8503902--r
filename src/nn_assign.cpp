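#include <Rcpp.h>
using namespace Rcpp;

// Nearest-centre label assignment. Coordinates are integer voxel indices,
// so squared Euclidean distances are exact; centre columns must arrive
// sorted by label so that the strict "<" update breaks ties toward the
// smaller label id.
// [[Rcpp::export(name = ".nn_assign_cpp")]]
IntegerVector nn_assign_cpp(IntegerMatrix mask_xyz, IntegerMatrix centre_xyz,
                            IntegerVector centre_label) {
  const int n = mask_xyz.nrow(), m = centre_xyz.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const int x = mask_xyz(i, 0), y = mask_xyz(i, 1), z = mask_xyz(i, 2);
    long long best = -1;
    int best_lab = 0;
    for (int j = 0; j < m; ++j) {
      const long long dx = x - centre_xyz(j, 0);
      const long long dy = y - centre_xyz(j, 1);
      const long long dz = z - centre_xyz(j, 2);
      const long long d2 = dx * dx + dy * dy + dz * dz;
      if (best < 0 || d2 < best) {
        best = d2;
        best_lab = centre_label[j];
        if (best == 0) break;
      }
    }
    out[i] = best_lab;
  }
  return out;
}
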
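// Random-walk blob growth for the synthetic lesion generator: starting
// from a seed voxel, voxels are added one at a time, each drawn uniformly
// from the 6-neighbour frontier of the current set, until the target size
// is reached (or the lattice boundary exhausts the frontier). The result
// is one 6-connected — hence 18-connected — component of exactly the
// requested size in the interior. Uses R's RNG stream, so growth is
// reproducible under set.seed().

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix grow_blob_cpp(IntegerVector dims, IntegerVector start,
                            int target) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (target < 1) stop("target size must be >= 1");
  auto lin = [&](int x, int y, int z) { return x + nx * (y + ny * z); };

  std::vector<char> state(static_cast<size_t>(nx) * ny * nz, 0);
  std::vector<int> members, cand;
  members.reserve(target);

  const int offs[6][3] = {{1, 0, 0}, {-1, 0, 0}, {0, 1, 0},
                          {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};
  auto push_neighbours = [&](int x, int y, int z) {
    for (const auto& o : offs) {
      const int ax = x + o[0], ay = y + o[1], az = z + o[2];
      if (ax < 0 || ax >= nx || ay < 0 || ay >= ny || az < 0 || az >= nz)
        continue;
      const int l = lin(ax, ay, az);
      if (!state[l]) { state[l] = 2; cand.push_back(l); }
    }
  };

  const int sx = start[0] - 1, sy = start[1] - 1, sz = start[2] - 1;
  if (sx < 0 || sx >= nx || sy < 0 || sy >= ny || sz < 0 || sz >= nz)
    stop("start voxel outside the lattice");
  members.push_back(lin(sx, sy, sz));
  state[members[0]] = 1;
  push_neighbours(sx, sy, sz);

  while (static_cast<int>(members.size()) < target && !cand.empty()) {
    int i = static_cast<int>(unif_rand() * cand.size());
    if (i >= static_cast<int>(cand.size())) i = cand.size() - 1;
    const int l = cand[i];
    cand[i] = cand.back();
    cand.pop_back();
    state[l] = 1;
    members.push_back(l);
    const int z = l / (nx * ny), r = l % (nx * ny);
    push_neighbours(r % nx, r / nx, z);
  }

  IntegerMatrix out(members.size(), 3);
  for (size_t i = 0; i < members.size(); ++i) {
    const int l = members[i], z = l / (nx * ny), r = l % (nx * ny);
    out(i, 0) = r % nx + 1;
    out(i, 1) = r / nx + 1;
    out(i, 2) = z + 1;
  }
  return out;
}
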
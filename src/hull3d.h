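#pragma once
#include <vector>
#include <array>

// Incremental 3D convex hull. Input: point coordinates; output: triangular
// facets as 0-based vertex index triples, oriented with outward normals.
// Throws (Rcpp::stop) on fewer than 4 points or a degenerate (coplanar) cloud.
std::vector<std::array<int, 3>> hull3d(const std::vector<std::array<double, 3>>& pts);
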
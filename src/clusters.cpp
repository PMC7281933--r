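#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Neighbour offsets in (dx, dy, dz) for the three standard 3D connectivities.
// 6: faces; 18: faces + edges; 26: full cube.
static std::vector<std::array<int, 3>> neighbour_offsets(int connectivity) {
    std::vector<std::array<int, 3>> offs;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                int manhattan = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (manhattan == 0) continue;
                if (connectivity == 6 && manhattan > 1) continue;
                if (connectivity == 18 && manhattan > 2) continue;
                offs.push_back({dx, dy, dz});
            }
    return offs;
}

// Label connected components of a 3D logical mask (column-major, dims nx,ny,nz).
// Labels are assigned in raster-scan order of each component's first voxel,
// so the labelling is deterministic. Background voxels get label 0.
// [[Rcpp::export]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dim, int connectivity) {
    if (dim.size() != 3) stop("dim must have length 3");
    if (connectivity != 6 && connectivity != 18 && connectivity != 26)
        stop("connectivity must be 6, 18 or 26");
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (mask.size() != n) stop("mask length does not match dim");

    std::vector<std::array<int, 3>> offs = neighbour_offsets(connectivity);
    IntegerVector labels(n, 0);
    std::vector<int> stack;
    int next_label = 0;

    for (R_xlen_t start = 0; start < n; ++start) {
        if (!mask[start] || labels[start] != 0) continue;
        ++next_label;
        labels[start] = next_label;
        stack.clear();
        stack.push_back((int)start);
        while (!stack.empty()) {
            int idx = stack.back();
            stack.pop_back();
            int x = idx % nx;
            int y = (idx / nx) % ny;
            int z = idx / (nx * ny);
            for (const auto &o : offs) {
                int xx = x + o[0], yy = y + o[1], zz = z + o[2];
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                    continue;
                int nidx = xx + nx * (yy + ny * zz);
                if (mask[nidx] && labels[nidx] == 0) {
                    labels[nidx] = next_label;
                    stack.push_back(nidx);
                }
            }
        }
    }
    labels.attr("dim") = dim;
    return labels;
}

// Size of the largest connected component (0 if the mask is empty).
// Used in permutation nulls where only the maximum extent matters.
// [[Rcpp::export]]
int cc_max_size(LogicalVector mask, IntegerVector dim, int connectivity) {
    IntegerVector labels = cc_label(mask, dim, connectivity);
    int nlab = 0;
    for (R_xlen_t i = 0; i < labels.size(); ++i)
        if (labels[i] > nlab) nlab = labels[i];
    if (nlab == 0) return 0;
    std::vector<int> counts(nlab + 1, 0);
    for (R_xlen_t i = 0; i < labels.size(); ++i) ++counts[labels[i]];
    int best = 0;
    for (int l = 1; l <= nlab; ++l)
        if (counts[l] > best) best = counts[l];
    return best;
}
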
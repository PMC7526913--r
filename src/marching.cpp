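// Iso-surface extraction by marching tetrahedra on the Kuhn (Freudenthal)
// subdivision of each grid cube. The subdivision is translation-consistent,
// and iso-vertices are deduplicated per grid edge (interpolating always from
// the lower global index), so the resulting mesh is watertight whenever the
// super-level region does not touch the array border (the R wrapper pads).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// Kuhn simplices of the unit cube; corner id = dx + 2*dy + 4*dz.
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
};

struct MeshAcc {
  std::vector<double> verts;            // x,y,z triples (grid coordinates)
  std::vector<int> faces;               // 1-based vertex ids
  std::unordered_map<uint64_t, int> edge_vertex;

  int vertex_on_edge(uint64_t gi, uint64_t gj,
                     const double *pi, const double *pj,
                     double fi, double fj, double level) {
    if (gi > gj) { std::swap(gi, gj); std::swap(pi, pj); std::swap(fi, fj); }
    uint64_t key = gi * 0x100000000ULL + gj; // grids here are far below 2^32
    std::unordered_map<uint64_t, int>::iterator it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = (fj == fi) ? 0.5 : (level - fi) / (fj - fi);
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    verts.push_back(pi[0] + t * (pj[0] - pi[0]));
    verts.push_back(pi[1] + t * (pj[1] - pi[1]));
    verts.push_back(pi[2] + t * (pj[2] - pi[2]));
    int id = (int)(verts.size() / 3); // 1-based
    edge_vertex[key] = id;
    return id;
  }

  void triangle(int a, int b, int c, const double *ref_in,
                const double *ref_out) {
    // orient so the normal points from the inside toward the outside
    const double *va = &verts[(a - 1) * 3];
    const double *vb = &verts[(b - 1) * 3];
    const double *vc = &verts[(c - 1) * 3];
    double u[3] = { vb[0] - va[0], vb[1] - va[1], vb[2] - va[2] };
    double w[3] = { vc[0] - va[0], vc[1] - va[1], vc[2] - va[2] };
    double n[3] = { u[1] * w[2] - u[2] * w[1],
                    u[2] * w[0] - u[0] * w[2],
                    u[0] * w[1] - u[1] * w[0] };
    double d[3] = { ref_out[0] - ref_in[0], ref_out[1] - ref_in[1],
                    ref_out[2] - ref_in[2] };
    double dot = n[0] * d[0] + n[1] * d[1] + n[2] * d[2];
    if (dot < 0) { int tmp = b; b = c; c = tmp; }
    faces.push_back(a); faces.push_back(b); faces.push_back(c);
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_marching_tetrahedra(NumericVector field, IntegerVector dim,
                             double level) {
  if (dim.size() != 3) stop("dim must have length 3");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  if ((R_xlen_t)nx * ny * nz != field.size())
    stop("field size does not match dim");
  MeshAcc acc;
  int cdx[8], cdy[8], cdz[8];
  for (int c = 0; c < 8; ++c) {
    cdx[c] = c & 1; cdy[c] = (c >> 1) & 1; cdz[c] = (c >> 2) & 1;
  }
  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        double f[8], px[8][3];
        uint64_t gid[8];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int xx = x + cdx[c], yy = y + cdy[c], zz = z + cdz[c];
          R_xlen_t i = (R_xlen_t)xx +
            (R_xlen_t)nx * ((R_xlen_t)yy + (R_xlen_t)ny * zz);
          f[c] = field[i];
          gid[c] = (uint64_t)i;
          px[c][0] = xx; px[c][1] = yy; px[c][2] = zz;
          if (f[c] > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = TETS[t];
          int in_ids[4], out_ids[4], n_in = 0, n_out = 0;
          for (int k = 0; k < 4; ++k) {
            if (f[T[k]] > level) in_ids[n_in++] = T[k];
            else out_ids[n_out++] = T[k];
          }
          if (n_in == 0 || n_in == 4) continue;
          double ref_in[3] = {0, 0, 0}, ref_out[3] = {0, 0, 0};
          for (int k = 0; k < n_in; ++k)
            for (int d = 0; d < 3; ++d) ref_in[d] += px[in_ids[k]][d] / n_in;
          for (int k = 0; k < n_out; ++k)
            for (int d = 0; d < 3; ++d) ref_out[d] += px[out_ids[k]][d] / n_out;
          if (n_in == 1) {
            int a = in_ids[0];
            int v0 = acc.vertex_on_edge(gid[a], gid[out_ids[0]], px[a],
                                        px[out_ids[0]], f[a], f[out_ids[0]],
                                        level);
            int v1 = acc.vertex_on_edge(gid[a], gid[out_ids[1]], px[a],
                                        px[out_ids[1]], f[a], f[out_ids[1]],
                                        level);
            int v2 = acc.vertex_on_edge(gid[a], gid[out_ids[2]], px[a],
                                        px[out_ids[2]], f[a], f[out_ids[2]],
                                        level);
            acc.triangle(v0, v1, v2, ref_in, ref_out);
          } else if (n_in == 3) {
            int a = out_ids[0];
            int v0 = acc.vertex_on_edge(gid[a], gid[in_ids[0]], px[a],
                                        px[in_ids[0]], f[a], f[in_ids[0]],
                                        level);
            int v1 = acc.vertex_on_edge(gid[a], gid[in_ids[1]], px[a],
                                        px[in_ids[1]], f[a], f[in_ids[1]],
                                        level);
            int v2 = acc.vertex_on_edge(gid[a], gid[in_ids[2]], px[a],
                                        px[in_ids[2]], f[a], f[in_ids[2]],
                                        level);
            acc.triangle(v0, v1, v2, ref_in, ref_out);
          } else { // 2 in, 2 out: quad (a,c),(a,d),(b,d),(b,c)
            int a = in_ids[0], b = in_ids[1];
            int c = out_ids[0], d = out_ids[1];
            int vac = acc.vertex_on_edge(gid[a], gid[c], px[a], px[c],
                                         f[a], f[c], level);
            int vad = acc.vertex_on_edge(gid[a], gid[d], px[a], px[d],
                                         f[a], f[d], level);
            int vbd = acc.vertex_on_edge(gid[b], gid[d], px[b], px[d],
                                         f[b], f[d], level);
            int vbc = acc.vertex_on_edge(gid[b], gid[c], px[b], px[c],
                                         f[b], f[c], level);
            acc.triangle(vac, vad, vbd, ref_in, ref_out);
            acc.triangle(vac, vbd, vbc, ref_in, ref_out);
          }
        }
      }
  int nv = (int)(acc.verts.size() / 3);
  int nf = (int)(acc.faces.size() / 3);
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nv; ++i)
    for (int d = 0; d < 3; ++d) V(i, d) = acc.verts[i * 3 + d];
  for (int i = 0; i < nf; ++i)
    for (int d = 0; d < 3; ++d) F(i, d) = acc.faces[i * 3 + d];
  return List::create(_["vertices"] = V, _["faces"] = F);
}
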
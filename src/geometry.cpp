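#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Closest point on triangle (a,b,c) to p, after Ericson, Real-Time
// Collision Detection ch. 5. Writes barycentric coords of the closest
// point into bary[0..2] and the point itself into out[0..2].
static double closest_on_triangle(const double *p,
                                  const double *a, const double *b,
                                  const double *c,
                                  double *out, double *bary) {
    double ab[3], ac[3], ap[3];
    for (int i = 0; i < 3; ++i) {
        ab[i] = b[i] - a[i];
        ac[i] = c[i] - a[i];
        ap[i] = p[i] - a[i];
    }
    double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
    double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
    double u = -1, v = -1; // barycentric weights of b and c

    if (d1 <= 0.0 && d2 <= 0.0) { u = 0; v = 0; }
    else {
        double bp[3];
        for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
        double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
        double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
        if (d3 >= 0.0 && d4 <= d3) { u = 1; v = 0; }
        else {
            double vc = d1*d4 - d3*d2;
            if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
                u = d1 / (d1 - d3); v = 0;
            } else {
                double cp[3];
                for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
                double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
                double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
                if (d6 >= 0.0 && d5 <= d6) { u = 0; v = 1; }
                else {
                    double vb = d5*d2 - d1*d6;
                    if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
                        u = 0; v = d2 / (d2 - d6);
                    } else {
                        double va = d3*d6 - d5*d4;
                        if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
                            double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
                            u = 1 - w; v = w;
                        } else {
                            double denom = 1.0 / (va + vb + vc);
                            u = vb * denom;
                            v = vc * denom;
                        }
                    }
                }
            }
        }
    }
    bary[0] = 1 - u - v; bary[1] = u; bary[2] = v;
    double d2sum = 0.0;
    for (int i = 0; i < 3; ++i) {
        out[i] = a[i] + u * ab[i] + v * ac[i];
        double diff = p[i] - out[i];
        d2sum += diff * diff;
    }
    return d2sum;
}

// Exact point-to-mesh distance for each row of P: minimum over every
// face (brute force; ties broken by the lowest face index because the
// comparison is strict). Faces are 1-based index triples into V.
// [[Rcpp::export]]
List cpp_point_mesh_distance(NumericMatrix P, NumericMatrix V,
                             IntegerMatrix F) {
    const int np = P.nrow(), nf = F.nrow();
    NumericVector dist(np);
    IntegerVector face(np);
    NumericMatrix closest(np, 3), bary(np, 3);
    std::vector<double> Vx(V.nrow()), Vy(V.nrow()), Vz(V.nrow());
    for (int i = 0; i < V.nrow(); ++i) {
        Vx[i] = V(i, 0); Vy[i] = V(i, 1); Vz[i] = V(i, 2);
    }
    for (int ip = 0; ip < np; ++ip) {
        double p[3] = { P(ip, 0), P(ip, 1), P(ip, 2) };
        double best = R_PosInf, bout[3] = {0, 0, 0}, bbar[3] = {1, 0, 0};
        int bface = 1;
        for (int f = 0; f < nf; ++f) {
            int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
            double a[3] = { Vx[ia], Vy[ia], Vz[ia] };
            double b[3] = { Vx[ib], Vy[ib], Vz[ib] };
            double c[3] = { Vx[ic], Vy[ic], Vz[ic] };
            double out[3], bar[3];
            double d2 = closest_on_triangle(p, a, b, c, out, bar);
            if (d2 < best) {
                best = d2; bface = f + 1;
                for (int i = 0; i < 3; ++i) { bout[i] = out[i]; bbar[i] = bar[i]; }
            }
        }
        dist[ip] = std::sqrt(best);
        face[ip] = bface;
        for (int i = 0; i < 3; ++i) {
            closest(ip, i) = bout[i];
            bary(ip, i) = bbar[i];
        }
    }
    return List::create(_["distance"] = dist, _["face"] = face,
                        _["closest"] = closest, _["barycentric"] = bary);
}

static inline int64_t cell_key(int ix, int iy, int iz) {
    // pack three 21-bit signed cell coordinates
    const int64_t off = 1 << 20;
    return (((int64_t)(ix + off)) << 42) |
           (((int64_t)(iy + off)) << 21) |
            ((int64_t)(iz + off));
}

// Dart-throwing Poisson-disk sampling on a triangle mesh. Faces are drawn
// with probability proportional to area, barycentric coordinates uniformly;
// a candidate is accepted iff no previously accepted sample lies within
// `radius`. Stops after `streak_limit` consecutive rejections. Uses R's RNG
// so results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_poisson_disk(NumericMatrix V, IntegerMatrix F, double radius,
                      int streak_limit) {
    RNGScope scope;
    const int nf = F.nrow();
    // cumulative face areas
    std::vector<double> cumarea(nf);
    double total = 0.0;
    for (int f = 0; f < nf; ++f) {
        int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
        double e1[3], e2[3];
        for (int i = 0; i < 3; ++i) {
            e1[i] = V(ib, i) - V(ia, i);
            e2[i] = V(ic, i) - V(ia, i);
        }
        double cx = e1[1]*e2[2] - e1[2]*e2[1];
        double cy = e1[2]*e2[0] - e1[0]*e2[2];
        double cz = e1[0]*e2[1] - e1[1]*e2[0];
        total += 0.5 * std::sqrt(cx*cx + cy*cy + cz*cz);
        cumarea[f] = total;
    }
    const double cell = radius / std::sqrt(3.0);
    const double r2 = radius * radius;
    std::unordered_map<int64_t, std::vector<int>> grid;
    std::vector<double> sx, sy, sz, sb0, sb1, sb2;
    std::vector<int> sface;

    int streak = 0;
    while (streak < streak_limit) {
        double u = unif_rand() * total;
        int f = (int)(std::lower_bound(cumarea.begin(), cumarea.end(), u) -
                      cumarea.begin());
        if (f >= nf) f = nf - 1;
        double r1 = std::sqrt(unif_rand()), rr2 = unif_rand();
        double b0 = 1.0 - r1, b1 = r1 * (1.0 - rr2), b2 = r1 * rr2;
        int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
        double px = b0*V(ia,0) + b1*V(ib,0) + b2*V(ic,0);
        double py = b0*V(ia,1) + b1*V(ib,1) + b2*V(ic,1);
        double pz = b0*V(ia,2) + b1*V(ib,2) + b2*V(ic,2);
        int cx = (int)std::floor(px / cell);
        int cy = (int)std::floor(py / cell);
        int cz = (int)std::floor(pz / cell);
        bool ok = true;
        for (int dx = -2; dx <= 2 && ok; ++dx)
            for (int dy = -2; dy <= 2 && ok; ++dy)
                for (int dz = -2; dz <= 2 && ok; ++dz) {
                    auto it = grid.find(cell_key(cx+dx, cy+dy, cz+dz));
                    if (it == grid.end()) continue;
                    for (int idx : it->second) {
                        double ddx = sx[idx] - px, ddy = sy[idx] - py,
                               ddz = sz[idx] - pz;
                        if (ddx*ddx + ddy*ddy + ddz*ddz < r2) {
                            ok = false; break;
                        }
                    }
                }
        if (ok) {
            int id = (int)sx.size();
            sx.push_back(px); sy.push_back(py); sz.push_back(pz);
            sb0.push_back(b0); sb1.push_back(b1); sb2.push_back(b2);
            sface.push_back(f + 1);
            grid[cell_key(cx, cy, cz)].push_back(id);
            streak = 0;
        } else {
            ++streak;
        }
    }
    int n = (int)sx.size();
    NumericMatrix pos(n, 3), bary(n, 3);
    IntegerVector face(n);
    for (int i = 0; i < n; ++i) {
        pos(i,0) = sx[i]; pos(i,1) = sy[i]; pos(i,2) = sz[i];
        bary(i,0) = sb0[i]; bary(i,1) = sb1[i]; bary(i,2) = sb2[i];
        face[i] = sface[i];
    }
    return List::create(_["positions"] = pos, _["face"] = face,
                        _["barycentric"] = bary);
}

// For each row of P, minimum distance to the closed polyline whose
// segments run A[i,] -> B[i,]; returns the distance, the realizing
// segment (1-based, lowest index on ties) and the closest point.
// [[Rcpp::export]]
List cpp_point_polyline_distance(NumericMatrix P, NumericMatrix A,
                                 NumericMatrix B) {
    const int np = P.nrow(), ns = A.nrow();
    NumericVector dist(np);
    IntegerVector seg(np);
    NumericMatrix closest(np, 3);
    for (int ip = 0; ip < np; ++ip) {
        double p[3] = { P(ip,0), P(ip,1), P(ip,2) };
        double best = R_PosInf, bout[3] = {0,0,0};
        int bseg = 1;
        for (int s = 0; s < ns; ++s) {
            double d[3], ap[3], len2 = 0.0, dot = 0.0;
            for (int i = 0; i < 3; ++i) {
                d[i] = B(s,i) - A(s,i);
                ap[i] = p[i] - A(s,i);
                len2 += d[i]*d[i];
                dot += d[i]*ap[i];
            }
            double t = (len2 > 0) ? dot / len2 : 0.0;
            if (t < 0) t = 0; else if (t > 1) t = 1;
            double q[3], d2 = 0.0;
            for (int i = 0; i < 3; ++i) {
                q[i] = A(s,i) + t * d[i];
                double diff = p[i] - q[i];
                d2 += diff * diff;
            }
            if (d2 < best) {
                best = d2; bseg = s + 1;
                for (int i = 0; i < 3; ++i) bout[i] = q[i];
            }
        }
        dist[ip] = std::sqrt(best);
        seg[ip] = bseg;
        for (int i = 0; i < 3; ++i) closest(ip, i) = bout[i];
    }
    return List::create(_["distance"] = dist, _["segment"] = seg,
                        _["closest"] = closest);
}

// Brute-force k nearest neighbours of each query row among the rows of
// ref; returns 1-based indices and distances, nearest first.
// [[Rcpp::export]]
List cpp_knn(NumericMatrix Q, NumericMatrix R, int k) {
    const int nq = Q.nrow(), nr = R.nrow();
    if (k > nr) k = nr;
    IntegerMatrix idx(nq, k);
    NumericMatrix dst(nq, k);
    std::vector<std::pair<double,int>> heap;
    for (int iq = 0; iq < nq; ++iq) {
        heap.clear();
        double qx = Q(iq,0), qy = Q(iq,1), qz = Q(iq,2);
        for (int ir = 0; ir < nr; ++ir) {
            double dx = R(ir,0)-qx, dy = R(ir,1)-qy, dz = R(ir,2)-qz;
            double d2 = dx*dx + dy*dy + dz*dz;
            if ((int)heap.size() < k) {
                heap.push_back({d2, ir});
                std::push_heap(heap.begin(), heap.end());
            } else if (d2 < heap.front().first) {
                std::pop_heap(heap.begin(), heap.end());
                heap.back() = {d2, ir};
                std::push_heap(heap.begin(), heap.end());
            }
        }
        std::sort_heap(heap.begin(), heap.end());
        for (int j = 0; j < k; ++j) {
            idx(iq, j) = heap[j].second + 1;
            dst(iq, j) = std::sqrt(heap[j].first);
        }
    }
    return List::create(_["index"] = idx, _["distance"] = dst);
}
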
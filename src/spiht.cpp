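// SPIHT (Said-Pearlman set partitioning in hierarchical trees) encoder and
// decoder over an integer Mallat coefficient plane, with exact bit-budget
// truncation.  The spatial-orientation tree uses coordinate doubling outside
// the coarsest LL band; inside the LL, 2x2 groups have a rootless top-left
// member while the other three members parent the co-located 2x2 blocks of
// the coarsest HL/LH/HH bands (this coincides with plain doubling when the
// LL is 2x2).
#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

struct StreamEnd {};  // budget hit (encode) or bits exhausted (decode)

class BitWriter {
public:
  std::vector<uint8_t> bits;
  long long budget;  // < 0 means unlimited
  explicit BitWriter(double b) {
    budget = (b < 0) ? -1 : (long long)b;
    if (budget >= 0) bits.reserve((size_t)budget);
  }
  inline void put(int b) {
    if (budget >= 0 && (long long)bits.size() >= budget) throw StreamEnd();
    bits.push_back((uint8_t)(b != 0));
  }
};

class BitReader {
  const uint8_t* p;
  R_xlen_t n, pos;
public:
  BitReader(const uint8_t* p_, R_xlen_t n_) : p(p_), n(n_), pos(0) {}
  inline int get() {
    if (pos >= n) throw StreamEnd();
    return p[pos++] != 0;
  }
};

struct Coord { int r, c; };
struct SetEntry { int r, c; uint8_t type; };  // type 0 = A, 1 = B

class Tree {
public:
  int H, W, Hll, Wll;
  Tree(int H_, int W_, int levels) : H(H_), W(W_) {
    Hll = H >> levels;
    Wll = W >> levels;
  }
  // Writes up to 4 offspring into out; returns count (0 or 4).
  inline int offspring(int r, int c, Coord* out) const {
    if (r < Hll && c < Wll) {
      if ((r & 1) == 0 && (c & 1) == 0) return 0;
      int a = r >> 1, b = c >> 1, r0, c0;
      if ((r & 1) == 0)      { r0 = 2 * a;       c0 = Wll + 2 * b; }
      else if ((c & 1) == 0) { r0 = Hll + 2 * a; c0 = 2 * b; }
      else                   { r0 = Hll + 2 * a; c0 = Wll + 2 * b; }
      out[0] = {r0, c0}; out[1] = {r0, c0 + 1};
      out[2] = {r0 + 1, c0}; out[3] = {r0 + 1, c0 + 1};
      return 4;
    }
    if (2 * r >= H || 2 * c >= W) return 0;
    out[0] = {2 * r, 2 * c};     out[1] = {2 * r, 2 * c + 1};
    out[2] = {2 * r + 1, 2 * c}; out[3] = {2 * r + 1, 2 * c + 1};
    return 4;
  }
};

// maxD(i,j): max magnitude over all descendants (excluding the node);
// maxL(i,j): max over descendants excluding direct offspring.  -1 = empty.
void descendant_maxima(const IntegerMatrix& mag, const Tree& tree,
                       IntegerMatrix& maxD, IntegerMatrix& maxL) {
  Coord off[4];
  for (int r = tree.H - 1; r >= 0; --r) {
    for (int c = tree.W - 1; c >= 0; --c) {
      int k = tree.offspring(r, c, off);
      int mD = -1, mL = -1;
      for (int i = 0; i < k; ++i) {
        int orr = off[i].r, occ = off[i].c;
        int childMag = mag(orr, occ);
        int childD = maxD(orr, occ);
        if (childMag > mD) mD = childMag;
        if (childD > mD) mD = childD;
        if (childD > mL) mL = childD;
      }
      maxD(r, c) = mD;
      maxL(r, c) = mL;
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".spiht_encode_cpp")]]
List spiht_encode_cpp(IntegerMatrix mag, IntegerMatrix sign, int levels,
                      double budget) {
  const int H = mag.nrow(), W = mag.ncol();
  Tree tree(H, W, levels);
  if (tree.Hll < 2 || tree.Wll < 2 || (tree.Hll & 1) || (tree.Wll & 1) ||
      (tree.Hll << levels) != H || (tree.Wll << levels) != W) {
    stop("plane dimensions incompatible with the level count");
  }
  int bmax = -1, peak = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (mag(i, j) > peak) peak = mag(i, j);
  while ((1 << (bmax + 1)) <= peak) ++bmax;

  BitWriter out(budget);
  if (bmax >= 0) {
    IntegerMatrix maxD(H, W), maxL(H, W);
    descendant_maxima(mag, tree, maxD, maxL);

    std::vector<Coord> LIP, LSP;
    std::vector<SetEntry> LIS;
    for (int r = 0; r < tree.Hll; ++r)
      for (int c = 0; c < tree.Wll; ++c) {
        LIP.push_back({r, c});
        if (!((r & 1) == 0 && (c & 1) == 0))
          LIS.push_back({r, c, 0});
      }

    Coord off[4];
    try {
      for (int n = bmax; n >= 0; --n) {
        const int T = 1 << n;
        const size_t lsp_old = LSP.size();
        // -- sorting pass: LIP
        std::vector<Coord> keep;
        keep.reserve(LIP.size());
        for (const Coord& p : LIP) {
          int sig = mag(p.r, p.c) >= T;
          out.put(sig);
          if (sig) {
            out.put(sign(p.r, p.c) < 0);
            LSP.push_back(p);
          } else keep.push_back(p);
        }
        LIP.swap(keep);
        // -- sorting pass: LIS (appended entries processed in this pass)
        for (size_t k = 0; k < LIS.size(); ++k) {
          SetEntry e = LIS[k];
          if (e.type == 0) {
            int sig = maxD(e.r, e.c) >= T;
            out.put(sig);
            if (!sig) continue;
            int cnt = tree.offspring(e.r, e.c, off);
            for (int i = 0; i < cnt; ++i) {
              int s = mag(off[i].r, off[i].c) >= T;
              out.put(s);
              if (s) {
                out.put(sign(off[i].r, off[i].c) < 0);
                LSP.push_back(off[i]);
              } else LIP.push_back(off[i]);
            }
            if (maxL(e.r, e.c) >= 0)
              LIS.push_back({e.r, e.c, 1});
            LIS[k].type = 2;  // mark removed
          } else if (e.type == 1) {
            int sig = maxL(e.r, e.c) >= T;
            out.put(sig);
            if (!sig) continue;
            int cnt = tree.offspring(e.r, e.c, off);
            for (int i = 0; i < cnt; ++i)
              LIS.push_back({off[i].r, off[i].c, 0});
            LIS[k].type = 2;
          }
        }
        {
          std::vector<SetEntry> kept;
          kept.reserve(LIS.size());
          for (const SetEntry& e : LIS)
            if (e.type != 2) kept.push_back(e);
          LIS.swap(kept);
        }
        // -- refinement pass over pixels significant before this plane
        for (size_t i = 0; i < lsp_old; ++i)
          out.put((mag(LSP[i].r, LSP[i].c) >> n) & 1);
      }
    } catch (StreamEnd&) {
      // truncated exactly at the budget
    }
  }
  RawVector bits(out.bits.size());
  for (R_xlen_t i = 0; i < (R_xlen_t)out.bits.size(); ++i)
    bits[i] = out.bits[i];
  return List::create(_["bits"] = bits, _["b_max"] = bmax,
                      _["nbits"] = (double)out.bits.size());
}

// [[Rcpp::export(name = ".spiht_decode_cpp")]]
NumericMatrix spiht_decode_cpp(RawVector bits, int H, int W, int levels,
                               int bmax) {
  Tree tree(H, W, levels);
  if (tree.Hll < 2 || tree.Wll < 2 || (tree.Hll & 1) || (tree.Wll & 1) ||
      (tree.Hll << levels) != H || (tree.Wll << levels) != W || bmax > 30) {
    stop("malformed stream header");
  }
  NumericMatrix rec(H, W);
  if (bmax < 0) return rec;

  // Decoder-side significance state of descendant sets: the decoder cannot
  // see magnitudes, so list dynamics are driven purely by the bits read;
  // rec tracks midpoint reconstructions.
  BitReader in(RAW(bits), bits.size());
  std::vector<Coord> LIP, LSP;
  std::vector<SetEntry> LIS;
  for (int r = 0; r < tree.Hll; ++r)
    for (int c = 0; c < tree.Wll; ++c) {
      LIP.push_back({r, c});
      if (!((r & 1) == 0 && (c & 1) == 0))
        LIS.push_back({r, c, 0});
    }

  Coord off[4];
  bool complete = true;
  try {
    for (int n = bmax; n >= 0; --n) {
      const double T = (double)(1 << n);
      const size_t lsp_old = LSP.size();
      std::vector<Coord> keep;
      keep.reserve(LIP.size());
      for (const Coord& p : LIP) {
        if (in.get()) {
          int neg = in.get();
          rec(p.r, p.c) = (neg ? -1.5 : 1.5) * T;
          LSP.push_back(p);
        } else keep.push_back(p);
      }
      LIP.swap(keep);
      for (size_t k = 0; k < LIS.size(); ++k) {
        SetEntry e = LIS[k];
        if (e.type == 0) {
          if (!in.get()) continue;
          int cnt = tree.offspring(e.r, e.c, off);
          bool hasL = false;
          for (int i = 0; i < cnt; ++i) {
            if (in.get()) {
              int neg = in.get();
              rec(off[i].r, off[i].c) = (neg ? -1.5 : 1.5) * T;
              LSP.push_back(off[i]);
            } else LIP.push_back(off[i]);
          }
          // L(i,j) nonempty iff any offspring has offspring of its own
          for (int i = 0; i < cnt && !hasL; ++i) {
            Coord tmp[4];
            hasL = tree.offspring(off[i].r, off[i].c, tmp) > 0;
          }
          if (hasL) LIS.push_back({e.r, e.c, 1});
          LIS[k].type = 2;
        } else if (e.type == 1) {
          if (!in.get()) continue;
          int cnt = tree.offspring(e.r, e.c, off);
          for (int i = 0; i < cnt; ++i)
            LIS.push_back({off[i].r, off[i].c, 0});
          LIS[k].type = 2;
        }
      }
      {
        std::vector<SetEntry> kept;
        kept.reserve(LIS.size());
        for (const SetEntry& e : LIS)
          if (e.type != 2) kept.push_back(e);
        LIS.swap(kept);
      }
      for (size_t i = 0; i < lsp_old; ++i) {
        int b = in.get();
        double step = T / 2.0;
        double v = rec(LSP[i].r, LSP[i].c);
        rec(LSP[i].r, LSP[i].c) = v + (v < 0 ? -1.0 : 1.0) * (b ? step : -step);
      }
    }
  } catch (StreamEnd&) {
    complete = false;
  }
  if (complete) {
    // A fully decoded stream pins every magnitude to [m, m+1); floor gives
    // exact integer recovery.
    for (size_t i = 0; i < LSP.size(); ++i) {
      double v = rec(LSP[i].r, LSP[i].c);
      double m = std::floor(std::fabs(v));
      rec(LSP[i].r, LSP[i].c) = (v < 0 ? -m : m);
    }
  }
  return rec;
}

// [[Rcpp::export(name = ".spiht_offspring_cpp")]]
IntegerMatrix spiht_offspring_cpp(int r, int c, int H, int W, int levels) {
  Tree tree(H, W, levels);
  Coord off[4];
  int k = tree.offspring(r, c, off);
  IntegerMatrix out(k, 2);
  for (int i = 0; i < k; ++i) {
    out(i, 0) = off[i].r;
    out(i, 1) = off[i].c;
  }
  return out;
}

// [[Rcpp::export(name = ".region_grow_cpp")]]
List region_grow_cpp(IntegerMatrix img, int seed_r, int seed_c, double tol) {
  const int H = img.nrow(), W = img.ncol();
  LogicalMatrix mask(H, W);
  std::vector<uint8_t> seen((size_t)H * W, 0);
  // fixed neighbour order: N, S, W, E, NW, NE, SW, SE
  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  std::vector<int> queue;
  queue.reserve((size_t)H * W);
  double sum = img(seed_r, seed_c);
  long long cnt = 1;
  mask(seed_r, seed_c) = true;
  seen[(size_t)seed_c * H + seed_r] = 1;
  queue.push_back(seed_c * H + seed_r);
  size_t head = 0;
  while (head < queue.size()) {
    int idx = queue[head++];
    int r = idx % H, c = idx / H;
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      size_t lin = (size_t)cc * H + rr;
      if (seen[lin]) continue;
      seen[lin] = 1;  // tested once, never revisited
      double mean = sum / (double)cnt;
      if (std::fabs((double)img(rr, cc) - mean) <= tol) {
        mask(rr, cc) = true;
        sum += img(rr, cc);
        ++cnt;
        queue.push_back(cc * H + rr);
      }
    }
  }
  return List::create(_["mask"] = mask, _["mean"] = sum / (double)cnt);
}
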
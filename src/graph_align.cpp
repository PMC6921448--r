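// Junction-aware affine local alignment of reads to a sequence DAG.
//
// Plain (non-striped) Gotoh dynamic programming where the recurrence at the
// first column of a node draws its predecessor cells from the last column of
// every in-neighbour node.  Scores are therefore identical to the maximum over
// linear Smith-Waterman alignments against all enumerable allele paths.
//
// States: H(i,c) best local alignment ending with read base i aligned to
// graph column c; E(i,c) ending with column c deleted (gap in the read);
// F(i,c) ending with read base i inserted (gap in the graph).

#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

typedef int16_t score_t;
static const score_t NEG = INT16_MIN / 4;

struct GraphLayout {
  std::string cols;                      // concatenated node sequences
  std::vector<int> col_node;             // node index per column
  std::vector<std::vector<int>> preds;   // predecessor columns per column
  std::vector<int> node_first, node_last;
};

static GraphLayout layout_graph(const std::vector<std::string> &node_seqs,
                                const List &in_neighbors) {
  GraphLayout g;
  int nn = node_seqs.size();
  g.node_first.resize(nn);
  g.node_last.resize(nn);
  for (int k = 0; k < nn; ++k) {
    g.node_first[k] = g.cols.size();
    g.cols += node_seqs[k];
    g.node_last[k] = g.cols.size() - 1;
    for (size_t j = g.node_first[k]; j < g.cols.size(); ++j)
      g.col_node.push_back(k);
  }
  int nc = g.cols.size();
  g.preds.assign(nc, {});
  for (int k = 0; k < nn; ++k) {
    IntegerVector nb = in_neighbors[k];
    for (int j = 0; j < nb.size(); ++j)
      g.preds[g.node_first[k]].push_back(g.node_last[nb[j]]);
    std::sort(g.preds[g.node_first[k]].begin(), g.preds[g.node_first[k]].end());
    for (int c = g.node_first[k] + 1; c <= g.node_last[k]; ++c)
      g.preds[c].push_back(c - 1);
  }
  return g;
}

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &ch : r) {
    switch (ch) {
      case 'A': ch = 'T'; break; case 'C': ch = 'G'; break;
      case 'G': ch = 'C'; break; case 'T': ch = 'A'; break;
      case 'a': ch = 't'; break; case 'c': ch = 'g'; break;
      case 'g': ch = 'c'; break; case 't': ch = 'a'; break;
      default: ch = 'N';
    }
  }
  return r;
}

struct Aln {
  int score, read_start, read_end, graph_start, graph_end, mismatches;
  char strand;
  std::vector<int> node_path;     // node indices (0-based)
  std::vector<int> node_overlap;  // aligned read bases per path node
};

class Aligner {
public:
  Aligner(const GraphLayout &g, int match, int mismatch, int go, int ge)
    : g_(g), ma_(match), mi_(mismatch), go_(go), ge_(ge) {}

  // DP over one oriented read; appends co-optimal alignments (up to cap,
  // endpoints scanned in column-major order) scoring exactly best_out.
  void align(const std::string &read, char strand, int cap,
             std::vector<Aln> &out, int &best_out) {
    const int m = read.size(), nc = g_.cols.size();
    const size_t sz = (size_t)(m + 1) * nc;
    if (H_.size() < sz) { H_.resize(sz); E_.resize(sz); F_.resize(sz); }
    int best = 0;
    for (int c = 0; c < nc; ++c) {
      const std::vector<int> &pr = g_.preds[c];
      const char gc = g_.cols[c];
      score_t *Hc = &H_[(size_t)c * (m + 1)];
      score_t *Ec = &E_[(size_t)c * (m + 1)];
      score_t *Fc = &F_[(size_t)c * (m + 1)];
      Hc[0] = 0; Ec[0] = NEG; Fc[0] = NEG;
      if (pr.size() == 1 && pr[0] == c - 1) {
        // fast path: single in-column predecessor
        const score_t *Hp = Hc - (m + 1), *Ep = Ec - (m + 1);
        for (int i = 1; i <= m; ++i) {
          int e = std::max(Hp[i] + go_ + ge_, Ep[i] + ge_);
          int f = std::max(Hc[i - 1] + go_ + ge_, Fc[i - 1] + ge_);
          int s = (read[i - 1] == gc) ? ma_ : mi_;
          int h = Hp[i - 1] + s;
          if (e > h) h = e;
          if (f > h) h = f;
          if (h < 0) h = 0;
          Hc[i] = (score_t)h; Ec[i] = (score_t)std::max(e, (int)NEG); Fc[i] = (score_t)std::max(f, (int)NEG);
          if (h > best) best = h;
        }
      } else {
        for (int i = 1; i <= m; ++i) {
          int e = NEG, dmax = 0;
          for (size_t q = 0; q < pr.size(); ++q) {
            const score_t *Hp = &H_[(size_t)pr[q] * (m + 1)];
            const score_t *Ep = &E_[(size_t)pr[q] * (m + 1)];
            e = std::max(e, std::max(Hp[i] + go_ + ge_, Ep[i] + ge_));
            dmax = std::max(dmax, (int)Hp[i - 1]);
          }
          int f = std::max(Hc[i - 1] + go_ + ge_, Fc[i - 1] + ge_);
          int s = (read[i - 1] == gc) ? ma_ : mi_;
          int h = dmax + s;
          if (e > h) h = e;
          if (f > h) h = f;
          if (h < 0) h = 0;
          Hc[i] = (score_t)h; Ec[i] = (score_t)std::max(e, (int)NEG); Fc[i] = (score_t)std::max(f, (int)NEG);
          if (h > best) best = h;
        }
      }
    }
    best_out = best;
    if (best <= 0) return;
    int found = 0;
    for (int c = 0; c < nc && found < cap; ++c) {
      const score_t *Hc = &H_[(size_t)c * (m + 1)];
      for (int i = 1; i <= m && found < cap; ++i) {
        if (Hc[i] == best) {
          out.push_back(traceback(read, strand, i, c));
          ++found;
        }
      }
    }
  }

private:
  Aln traceback(const std::string &read, char strand, int ei, int ec) {
    const int m = read.size();
    auto H = [&](int i, int c) { return H_[(size_t)c * (m + 1) + i]; };
    auto E = [&](int i, int c) { return E_[(size_t)c * (m + 1) + i]; };
    auto F = [&](int i, int c) { return F_[(size_t)c * (m + 1) + i]; };
    Aln a; a.score = H(ei, ec); a.strand = strand;
    a.read_end = ei; a.graph_end = ec; a.mismatches = 0;
    std::vector<int> cols;               // columns consumed (reverse order)
    std::vector<bool> aligned;           // diagonal (read base paired)?
    int i = ei, c = ec, state = 0;       // 0=H 1=E 2=F
    int read_start = ei, graph_start = ec;
    while (true) {
      if (state == 0) {
        int val = H(i, c);
        int s = (read[i - 1] == g_.cols[c]) ? ma_ : mi_;
        int need = val - s;
        bool moved = false;
        for (size_t q = 0; q < g_.preds[c].size() && !moved; ++q) {
          int p = g_.preds[c][q];
          if (i >= 2 && H(i - 1, p) == need && need > 0) {
            cols.push_back(c); aligned.push_back(true);
            if (s == mi_) ++a.mismatches;
            i -= 1; c = p; moved = true;
          }
        }
        if (moved) continue;
        if (need == 0 && s > 0) {        // alignment starts here
          cols.push_back(c); aligned.push_back(true);
          read_start = i; graph_start = c;
          break;
        }
        if (need == 0 && s <= 0) {       // start on a mismatch: impossible for
          cols.push_back(c); aligned.push_back(true);  // best>0, keep safe
          if (s == mi_) ++a.mismatches;
          read_start = i; graph_start = c;
          break;
        }
        if (E(i, c) == val) { state = 1; continue; }
        if (F(i, c) == val) { state = 2; continue; }
        // diagonal from a zero cell (fresh start consuming this pair)
        cols.push_back(c); aligned.push_back(true);
        if (s == mi_) ++a.mismatches;
        read_start = i; graph_start = c;
        break;
      } else if (state == 1) {
        int val = E(i, c);
        cols.push_back(c); aligned.push_back(false);
        bool moved = false;
        for (size_t q = 0; q < g_.preds[c].size() && !moved; ++q) {
          int p = g_.preds[c][q];
          if (H(i, p) + go_ + ge_ == val) { c = p; state = 0; moved = true; }
        }
        if (moved) continue;
        for (size_t q = 0; q < g_.preds[c].size() && !moved; ++q) {
          int p = g_.preds[c][q];
          if (E(i, p) + ge_ == val) { c = p; moved = true; }
        }
        if (!moved) Rcpp::stop("traceback failure (E state)");
      } else {
        int val = F(i, c);
        if (H(i - 1, c) + go_ + ge_ == val) { i -= 1; state = 0; }
        else if (F(i - 1, c) + ge_ == val) { i -= 1; }
        else Rcpp::stop("traceback failure (F state)");
      }
    }
    a.read_start = read_start;
    a.graph_start = graph_start;
    std::reverse(cols.begin(), cols.end());
    std::reverse(aligned.begin(), aligned.end());
    for (size_t j = 0; j < cols.size(); ++j) {
      int node = g_.col_node[cols[j]];
      if (a.node_path.empty() || a.node_path.back() != node) {
        a.node_path.push_back(node);
        a.node_overlap.push_back(0);
      }
      if (aligned[j]) a.node_overlap.back() += 1;
    }
    return a;
  }

  const GraphLayout &g_;
  int ma_, mi_, go_, ge_;
  std::vector<score_t> H_, E_, F_;
};

// [[Rcpp::export(name = ".graph_align_batch")]]
List graph_align_batch(CharacterVector reads,
                       CharacterVector node_seqs,
                       List in_neighbors,
                       int match, int mismatch, int gap_open, int gap_extend,
                       int max_alignments) {
  std::vector<std::string> seqs(node_seqs.size());
  for (int k = 0; k < node_seqs.size(); ++k)
    seqs[k] = as<std::string>(node_seqs[k]);
  GraphLayout g = layout_graph(seqs, in_neighbors);
  Aligner al(g, match, mismatch, gap_open, gap_extend);

  List res(reads.size());
  for (int r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    if (fwd.empty()) stop("empty read");
    std::string rev = revcomp_str(fwd);
    std::vector<Aln> af, ar;
    int bf = 0, br = 0;
    al.align(fwd, '+', max_alignments, af, bf);
    al.align(rev, '-', max_alignments, ar, br);
    std::vector<Aln> keep;
    if (bf > br) keep = af;
    else if (br > bf) keep = ar;
    else { keep = af; keep.insert(keep.end(), ar.begin(), ar.end()); }
    if ((int)keep.size() > max_alignments) keep.resize(max_alignments);
    List out(keep.size());
    for (size_t j = 0; j < keep.size(); ++j) {
      const Aln &a = keep[j];
      out[j] = List::create(
        _["score"] = a.score,
        _["strand"] = std::string(1, a.strand),
        _["read_start"] = a.read_start,
        _["read_end"] = a.read_end,
        _["graph_start"] = a.graph_start,
        _["graph_end"] = a.graph_end,
        _["mismatches"] = a.mismatches,
        _["node_path"] = IntegerVector(a.node_path.begin(), a.node_path.end()),
        _["node_overlap"] = IntegerVector(a.node_overlap.begin(),
                                          a.node_overlap.end()));
    }
    res[r] = out;
  }
  return res;
}
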
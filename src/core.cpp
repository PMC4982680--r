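// Core engine: compact carbon-skeleton representation of C/H carbocations,
// canonical labeling (individualization-refinement), SMILES emission, the
// five rearrangement operators + allylic resonance, and the breadth-first
// closure kernel. Hydrogens are implicit here (derived from valence); the
// R layer materializes them for the explicit-H user-facing graphs.
#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <queue>
#include <unordered_map>
#include <unordered_set>
#include <set>
#include <array>
#include <algorithm>
using namespace Rcpp;

static const int MAXN = 16;

struct Mol {
  int n;                    // number of carbons
  int chg;                  // 0-based index of the cationic carbon, -1 if neutral
  uint8_t bo[MAXN][MAXN];   // bond orders 0/1/2, symmetric, zero diagonal

  Mol() : n(0), chg(-1) { std::fill(&bo[0][0], &bo[0][0] + MAXN * MAXN, 0); }
};

static inline int rowsum(const Mol& m, int i) {
  int s = 0;
  for (int j = 0; j < m.n; ++j) s += m.bo[i][j];
  return s;
}
static inline int cap(const Mol& m, int i) { return (i == m.chg) ? 3 : 4; }
static inline int hcount(const Mol& m, int i) { return cap(m, i) - rowsum(m, i); }
static inline int heavy_deg(const Mol& m, int i) {
  int d = 0;
  for (int j = 0; j < m.n; ++j) if (m.bo[i][j] > 0) ++d;
  return d;
}
static inline bool in_double(const Mol& m, int i) {
  for (int j = 0; j < m.n; ++j) if (m.bo[i][j] == 2) return true;
  return false;
}

static bool connected(const Mol& m) {
  if (m.n <= 1) return true;
  std::vector<char> seen(m.n, 0);
  std::vector<int> st;
  st.push_back(0);
  seen[0] = 1;
  int cnt = 1;
  while (!st.empty()) {
    int u = st.back(); st.pop_back();
    for (int v = 0; v < m.n; ++v)
      if (m.bo[u][v] > 0 && !seen[v]) { seen[v] = 1; ++cnt; st.push_back(v); }
  }
  return cnt == m.n;
}

// Full structural validity of a (possibly charged) C/H species.
static std::string invalid_reason(const Mol& m) {
  if (m.n < 1) return "empty graph";
  if (m.chg >= m.n) return "charge index out of range";
  for (int i = 0; i < m.n; ++i) {
    if (m.bo[i][i] != 0) return "self bond";
    for (int j = 0; j < m.n; ++j) {
      if (m.bo[i][j] != m.bo[j][i]) return "asymmetric bond matrix";
      if (m.bo[i][j] > 2) return "bond order > 2";
    }
    if (rowsum(m, i) > cap(m, i)) return "valence exceeded";
  }
  if (m.chg >= 0 && in_double(m, m.chg)) return "cationic carbon in a double bond";
  if (!connected(m)) return "disconnected graph";
  return "";
}

// ---------------------------------------------------------------------------
// Canonical labeling: iterative colour refinement with individualization on
// ties, minimizing a serialized adjacency code. Graphs here have <= 10-12
// vertices so the search tree is tiny.
// ---------------------------------------------------------------------------

static void refine(const Mol& m, std::vector<int>& col) {
  const int n = m.n;
  for (;;) {
    // signature: own colour + sorted multiset of (bond order, neighbour colour)
    std::vector<std::vector<int> > sig(n);
    for (int i = 0; i < n; ++i) {
      sig[i].push_back(col[i]);
      std::vector<int> nb;
      for (int j = 0; j < n; ++j)
        if (m.bo[i][j] > 0) nb.push_back(m.bo[i][j] * 4096 + col[j]);
      std::sort(nb.begin(), nb.end());
      sig[i].insert(sig[i].end(), nb.begin(), nb.end());
    }
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(), [&](int a, int b) { return sig[a] < sig[b]; });
    std::vector<int> ncol(n);
    int c = 0;
    ncol[idx[0]] = 0;
    for (int k = 1; k < n; ++k) {
      if (sig[idx[k]] != sig[idx[k - 1]]) ++c;
      ncol[idx[k]] = c;
    }
    if (ncol == col) return;
    col = ncol;
  }
}

static std::string encode_ordered(const Mol& m, const std::vector<int>& order) {
  // order[k] = original index placed at canonical position k
  const int n = m.n;
  std::vector<int> pos(n);
  for (int k = 0; k < n; ++k) pos[order[k]] = k;
  std::string code;
  code.reserve(2 + n * (n - 1) / 2);
  code.push_back((char)n);
  code.push_back((char)(m.chg >= 0 ? pos[m.chg] : 127));
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b)
      code.push_back((char)m.bo[order[a]][order[b]]);
  return code;
}

struct CanonResult {
  std::string code;
  std::vector<int> order;
};

static void canon_search(const Mol& m, std::vector<int> col, CanonResult& best) {
  refine(m, col);
  const int n = m.n;
  // find the first non-singleton colour class (smallest colour value)
  int ncolors = 0;
  for (int i = 0; i < n; ++i) ncolors = std::max(ncolors, col[i] + 1);
  std::vector<int> count(ncolors, 0);
  for (int i = 0; i < n; ++i) count[col[i]]++;
  int target = -1;
  for (int c = 0; c < ncolors; ++c) if (count[c] > 1) { target = c; break; }
  if (target < 0) {
    // discrete partition: ordering by colour
    std::vector<int> order(n);
    for (int i = 0; i < n; ++i) order[col[i]] = i;
    std::string code = encode_ordered(m, order);
    if (best.code.empty() || code < best.code) { best.code = code; best.order = order; }
    return;
  }
  for (int v = 0; v < n; ++v) {
    if (col[v] != target) continue;
    std::vector<int> c2(col);
    // individualize v: give it a colour just below its class
    for (int i = 0; i < n; ++i) if (c2[i] >= target) c2[i]++;
    c2[v] = target;
    canon_search(m, c2, best);
  }
}

static CanonResult canonical(const Mol& m) {
  std::vector<int> col(m.n);
  for (int i = 0; i < m.n; ++i) col[i] = (i == m.chg) ? 1 : 0;
  CanonResult best;
  canon_search(m, col, best);
  return best;
}

static Mol relabel(const Mol& m, const std::vector<int>& order) {
  Mol r;
  r.n = m.n;
  std::vector<int> pos(m.n);
  for (int k = 0; k < m.n; ++k) pos[order[k]] = k;
  r.chg = (m.chg >= 0) ? pos[m.chg] : -1;
  for (int a = 0; a < m.n; ++a)
    for (int b = 0; b < m.n; ++b)
      r.bo[pos[a]][pos[b]] = m.bo[a][b];
  return r;
}

// ---------------------------------------------------------------------------
// SMILES writer. Assumes the labeling passed in (canonical labels give a
// canonical string). C/H only; charge as bracket atom with explicit H count.
// ---------------------------------------------------------------------------

struct SmilesCtx {
  const Mol* m;
  std::vector<char> visited;
  std::vector<int> parent;
  // ring closure digits per atom: (digit, bond order), in opening order
  std::vector<std::vector<std::pair<int, int> > > ringd;
  std::set<std::pair<int, int> > ring_pairs;
  int next_digit;
};

static void smiles_scan(SmilesCtx& c, int u) {
  c.visited[u] = 1;
  for (int v = 0; v < c.m->n; ++v) {
    if (c.m->bo[u][v] == 0) continue;
    if (!c.visited[v]) {
      c.parent[v] = u;
      smiles_scan(c, v);
    } else if (v != c.parent[u]) {
      std::pair<int, int> pr(std::min(u, v), std::max(u, v));
      if (c.ring_pairs.insert(pr).second) {
        if (c.next_digit > 9) Rcpp::stop("too many ring closures");
        int d = c.next_digit++;
        c.ringd[u].push_back(std::make_pair(d, c.m->bo[u][v]));
        c.ringd[v].push_back(std::make_pair(d, c.m->bo[u][v]));
      }
    }
  }
}

static std::string atom_token(const Mol& m, int i) {
  if (i != m.chg) return "C";
  int h = hcount(m, i);
  switch (h) {
    case 0: return "[C+]";
    case 1: return "[CH+]";
    case 2: return "[CH2+]";
    default: return "[CH3+]";
  }
}

static void smiles_emit(SmilesCtx& c, int u, std::string& out) {
  out += atom_token(*c.m, u);
  for (auto& p : c.ringd[u]) {
    if (p.second == 2) out += "=";
    out += (char)('0' + p.first);
  }
  std::vector<int> kids;
  for (int v = 0; v < c.m->n; ++v)
    if (c.m->bo[u][v] > 0 && c.parent[v] == u) kids.push_back(v);
  for (size_t k = 0; k < kids.size(); ++k) {
    int v = kids[k];
    std::string bond = (c.m->bo[u][v] == 2) ? "=" : "";
    if (k + 1 < kids.size()) {
      out += "(" + bond;
      smiles_emit(c, v, out);
      out += ")";
    } else {
      out += bond;
      smiles_emit(c, v, out);
    }
  }
}

static std::string write_smiles(const Mol& m) {
  SmilesCtx c;
  c.m = &m;
  c.visited.assign(m.n, 0);
  c.parent.assign(m.n, -1);
  c.ringd.assign(m.n, std::vector<std::pair<int, int> >());
  c.next_digit = 1;
  smiles_scan(c, 0);
  std::string out;
  smiles_emit(c, 0, out);
  return out;
}

// ---------------------------------------------------------------------------
// Cation classification (on the implicit-H skeleton)
// ---------------------------------------------------------------------------

// returns 1/2/3 (primary/secondary/tertiary) + 10 if allylic
static int classify(const Mol& m) {
  if (m.chg < 0) return 0;
  int d = heavy_deg(m, m.chg);
  int base = (d <= 1) ? 1 : (d == 2 ? 2 : 3);
  bool allylic = false;
  for (int a = 0; a < m.n; ++a) {
    if (m.bo[m.chg][a] == 0) continue;
    if (in_double(m, a)) allylic = true;
  }
  return base + (allylic ? 10 : 0);
}

// ---------------------------------------------------------------------------
// Reaction operators. Each returns candidate products with event atoms in the
// reactant's labeling. Types follow the field's numbering: 1 alkylation,
// 2 alkyl shift, 3 hydride shift, 4 methyl shift, 5 proton transfer,
// 6 resonance (zero-step bookkeeping edge).
// ---------------------------------------------------------------------------

struct Cand {
  Mol mol;
  int type;
  int a1, a2; // participating carbons, reactant labeling (0-based)
};

static inline bool reactive_carbon(const Mol& m, int i) {
  return i != m.chg && m.bo[m.chg][i] == 0;
}

static void bfs_dist(const Mol& m, int src, std::vector<int>& d) {
  d.assign(m.n, -1);
  std::queue<int> q;
  d[src] = 0;
  q.push(src);
  while (!q.empty()) {
    int u = q.front(); q.pop();
    for (int v = 0; v < m.n; ++v)
      if (m.bo[u][v] > 0 && d[v] < 0) { d[v] = d[u] + 1; q.push(v); }
  }
}

static void op_alkylation(const Mol& m, std::vector<Cand>& out) {
  for (int a = 0; a < m.n; ++a)
    for (int b = 0; b < m.n; ++b) {
      if (m.bo[a][b] != 2) continue; // ordered pairs: (a,b) and (b,a) both seen
      int t = a, o = b;              // attack t, charge lands on o
      // both alkene carbons must be outside the excluded set: an alkene
      // conjugated to the cation is the allylic resonance system, and its
      // charge interaction is the zero-step resonance edge, not a cyclization
      if (!reactive_carbon(m, t) || !reactive_carbon(m, o)) continue;
      Cand c;
      c.mol = m;
      c.mol.bo[a][b] = c.mol.bo[b][a] = 1;
      c.mol.bo[m.chg][t] = c.mol.bo[t][m.chg] = 1;
      c.mol.chg = o;
      c.type = 1; c.a1 = m.chg; c.a2 = t;
      out.push_back(c);
    }
}

static void op_shift_carbon(const Mol& m, bool methyl, std::vector<Cand>& out) {
  for (int ca = 0; ca < m.n; ++ca) {
    if (m.bo[m.chg][ca] != 1) continue;
    for (int mg = 0; mg < m.n; ++mg) {
      if (mg == m.chg || m.bo[ca][mg] != 1) continue;
      if (!reactive_carbon(m, mg)) continue;
      bool is_methyl = (hcount(m, mg) == 3);
      if (is_methyl != methyl) continue;
      Cand c;
      c.mol = m;
      c.mol.bo[ca][mg] = c.mol.bo[mg][ca] = 0;
      c.mol.bo[m.chg][mg] = c.mol.bo[mg][m.chg] = 1;
      c.mol.chg = ca;
      c.type = methyl ? 4 : 2; c.a1 = mg; c.a2 = ca;
      out.push_back(c);
    }
  }
}

static void op_hydride(const Mol& m, int range, std::vector<Cand>& out) {
  std::vector<int> d;
  if (range >= 0) bfs_dist(m, m.chg, d);
  for (int co = 0; co < m.n; ++co) {
    if (co == m.chg || hcount(m, co) < 1) continue;
    // H atoms on the cation's bonded atoms are excluded; H on any other
    // carbon (including alpha carbons) is reactive.
    if (range >= 0 && d[co] > range) continue;
    Cand c;
    c.mol = m;
    c.mol.chg = co;
    c.type = 3; c.a1 = co; c.a2 = m.chg;
    out.push_back(c);
  }
}

static void op_proton_transfer(const Mol& m, int range, std::vector<Cand>& out) {
  for (int cd = 0; cd < m.n; ++cd) {
    if (m.bo[m.chg][cd] != 1 || hcount(m, cd) < 1) continue;
    std::vector<int> d;
    if (range >= 0) bfs_dist(m, cd, d);
    for (int a = 0; a < m.n; ++a)
      for (int b = 0; b < m.n; ++b) {
        if (m.bo[a][b] != 2) continue;
        // an acceptor alkene containing the donor degenerates to an
        // allylic resonance shift, which is a zero-step edge, not type 5
        if (a == cd || b == cd) continue;
        int ac = a, oc = b; // proton to ac, charge lands on oc
        if (range >= 0 && d[ac] > range) continue;
        Cand c;
        c.mol = m;
        c.mol.bo[cd][m.chg] = c.mol.bo[m.chg][cd] = 2;
        c.mol.bo[a][b] = c.mol.bo[b][a] = 1;
        c.mol.chg = oc;
        c.type = 5; c.a1 = cd; c.a2 = ac;
        out.push_back(c);
      }
  }
}

static void op_resonance(const Mol& m, std::vector<Cand>& out) {
  for (int a = 0; a < m.n; ++a) {
    if (m.bo[m.chg][a] != 1) continue;
    for (int b = 0; b < m.n; ++b) {
      if (m.bo[a][b] != 2) continue;
      Cand c;
      c.mol = m;
      c.mol.bo[m.chg][a] = c.mol.bo[a][m.chg] = 2;
      c.mol.bo[a][b] = c.mol.bo[b][a] = 1;
      c.mol.chg = b;
      c.type = 6; c.a1 = m.chg; c.a2 = b;
      out.push_back(c);
    }
  }
}

static void expand(const Mol& m, const std::vector<int>& types, int range,
                   std::vector<Cand>& out) {
  for (int t : types) {
    switch (t) {
      case 1: op_alkylation(m, out); break;
      case 2: op_shift_carbon(m, false, out); break;
      case 3: op_hydride(m, range, out); break;
      case 4: op_shift_carbon(m, true, out); break;
      case 5: op_proton_transfer(m, range, out); break;
      default: break; // resonance handled by the insertion closure
    }
  }
}

// ---------------------------------------------------------------------------
// R <-> C++ molecule encoding: list(n =, charge =, bo = n x n integer matrix),
// charge 1-based or NA/0 for neutral.
// ---------------------------------------------------------------------------

static Mol mol_from_r(List x) {
  Mol m;
  m.n = as<int>(x["n"]);
  if (m.n < 1 || m.n > MAXN - 1) stop("molecule size out of range");
  SEXP ch = x["charge"];
  int chg1 = (Rf_isNull(ch) || IntegerVector(ch).size() == 0) ? 0 : as<int>(ch);
  if (chg1 == NA_INTEGER) chg1 = 0;
  m.chg = chg1 - 1;
  IntegerMatrix bo = x["bo"];
  if (bo.nrow() != m.n || bo.ncol() != m.n) stop("bond matrix dimension mismatch");
  for (int i = 0; i < m.n; ++i)
    for (int j = 0; j < m.n; ++j)
      m.bo[i][j] = (uint8_t)bo(i, j);
  return m;
}

static List mol_to_r(const Mol& m) {
  IntegerMatrix bo(m.n, m.n);
  for (int i = 0; i < m.n; ++i)
    for (int j = 0; j < m.n; ++j)
      bo(i, j) = m.bo[i][j];
  return List::create(_["n"] = m.n, _["charge"] = m.chg + 1, _["bo"] = bo);
}

// [[Rcpp::export]]
List cpp_canon(List mol) {
  Mol m = mol_from_r(mol);
  std::string err = invalid_reason(m);
  if (!err.empty()) stop("invalid molecule: " + err);
  CanonResult cr = canonical(m);
  Mol cm = relabel(m, cr.order);
  IntegerVector ord(m.n);
  for (int k = 0; k < m.n; ++k) ord[k] = cr.order[k] + 1;
  return List::create(_["smiles"] = write_smiles(cm),
                      _["order"] = ord,
                      _["mol"] = mol_to_r(cm));
}

// [[Rcpp::export]]
std::string cpp_validate(List mol) {
  Mol m = mol_from_r(mol);
  return invalid_reason(m);
}

// [[Rcpp::export]]
List cpp_expand(List mol, IntegerVector types, int shift_range) {
  Mol m = mol_from_r(mol);
  std::string err = invalid_reason(m);
  if (!err.empty()) stop("invalid molecule: " + err);
  if (m.chg < 0) stop("neutral species has no reactions");
  std::vector<int> tv(types.begin(), types.end());
  std::vector<Cand> cands;
  expand(m, tv, shift_range, cands);
  bool want_res = std::find(tv.begin(), tv.end(), 6) != tv.end();
  if (want_res) op_resonance(m, cands);
  List out;
  for (auto& c : cands) {
    if (!invalid_reason(c.mol).empty()) continue;
    out.push_back(List::create(_["mol"] = mol_to_r(c.mol),
                               _["type"] = c.type,
                               _["a1"] = c.a1 + 1, _["a2"] = c.a2 + 1));
  }
  return out;
}

// [[Rcpp::export]]
int cpp_classify(List mol) {
  Mol m = mol_from_r(mol);
  return classify(m);
}

// ---------------------------------------------------------------------------
// Skeleton extraction: neutralize (hydride quench), drop H, prune saturated
// degree-1 carbons to fixpoint, canonicalize the remaining framework.
// ---------------------------------------------------------------------------

static Mol skeleton_of(const Mol& m0) {
  Mol m = m0;
  m.chg = -1; // hydride quench: one H lands on the old cation centre
  std::vector<char> keep(m.n, 1);
  bool changed = true;
  while (changed) {
    changed = false;
    for (int i = 0; i < m.n; ++i) {
      if (!keep[i]) continue;
      int deg = 0; bool dbl = false;
      for (int j = 0; j < m.n; ++j) {
        if (!keep[j] || m.bo[i][j] == 0) continue;
        ++deg;
        if (m.bo[i][j] == 2) dbl = true;
      }
      if (deg <= 1 && !dbl) { keep[i] = 0; changed = true; }
    }
  }
  Mol s;
  std::vector<int> map(m.n, -1);
  int k = 0;
  for (int i = 0; i < m.n; ++i) if (keep[i]) map[i] = k++;
  s.n = k;
  s.chg = -1;
  for (int i = 0; i < m.n; ++i)
    for (int j = 0; j < m.n; ++j)
      if (keep[i] && keep[j]) s.bo[map[i]][map[j]] = m.bo[i][j];
  return s;
}

// [[Rcpp::export]]
List cpp_skeleton(List mol) {
  Mol m = mol_from_r(mol);
  std::string err = invalid_reason(m);
  if (!err.empty()) stop("invalid molecule: " + err);
  Mol s = skeleton_of(m);
  if (s.n == 0)
    return List::create(_["smiles"] = "", _["mol"] = R_NilValue);
  CanonResult cr = canonical(s);
  Mol cs = relabel(s, cr.order);
  return List::create(_["smiles"] = write_smiles(cs), _["mol"] = mol_to_r(cs));
}

// ---------------------------------------------------------------------------
// Breadth-first closure kernel.
// filter_mode: 0 permissive, 1 heuristic (reject classes in reject_mask
// unless allylic; mask bit 1 = primary, bit 2 = secondary).
// ---------------------------------------------------------------------------

struct Store {
  std::vector<Mol> mols;              // canonical labeling
  std::vector<std::string> codes;
  std::vector<int> rounds;
  std::vector<int> classes;
  std::unordered_map<std::string, int> index;
  std::vector<std::array<int, 5> > edges; // from,to,type,a1,a2 (0-based nodes)
  std::unordered_set<std::string> edge_seen;
};

static bool pass_filter(int cls, int filter_mode, int reject_mask) {
  if (filter_mode == 0) return true;
  bool allylic = cls >= 10;
  int base = cls % 10;
  if (allylic) return true;
  if (base == 1 && (reject_mask & 1)) return false;
  if (base == 2 && (reject_mask & 2)) return false;
  return true;
}

static void add_edge(Store& st, int from, int to, int type, int a1, int a2) {
  std::string key = std::to_string(from) + "," + std::to_string(to) + "," +
                    std::to_string(type) + "," + std::to_string(a1) + "," +
                    std::to_string(a2);
  if (st.edge_seen.insert(key).second)
    st.edges.push_back({{from, to, type, a1, a2}});
}

// Insert a node (already canonical); then close over resonance partners at
// the same round via zero-step edges. Returns node id, or -1 if filtered.
static int insert_node(Store& st, const Mol& cm, const std::string& code,
                       int round, int filter_mode, int reject_mask,
                       bool resonance_on, bool force) {
  auto it = st.index.find(code);
  if (it != st.index.end()) return it->second;
  int cls = classify(cm);
  if (!force && !pass_filter(cls, filter_mode, reject_mask)) return -1;
  int id = (int)st.mols.size();
  st.mols.push_back(cm);
  st.codes.push_back(code);
  st.rounds.push_back(round);
  st.classes.push_back(cls);
  st.index[code] = id;
  if (resonance_on && cm.chg >= 0) {
    std::vector<Cand> res;
    op_resonance(cm, res);
    for (auto& c : res) {
      if (!invalid_reason(c.mol).empty()) continue;
      CanonResult cr = canonical(c.mol);
      if (cr.code == code) continue; // degenerate (symmetric allyl)
      Mol pm = relabel(c.mol, cr.order);
      int pid = insert_node(st, pm, cr.code, round, filter_mode, reject_mask,
                            resonance_on, force);
      if (pid >= 0) add_edge(st, id, pid, 6, c.a1, c.a2);
    }
  }
  return id;
}

// [[Rcpp::export]]
List cpp_enumerate(List seeds, IntegerVector types, int shift_range,
                   int max_rounds, int filter_mode, int reject_mask) {
  std::vector<int> tv(types.begin(), types.end());
  bool resonance_on = std::find(tv.begin(), tv.end(), 6) != tv.end();
  Store st;
  for (int s = 0; s < seeds.size(); ++s) {
    Mol m = mol_from_r(seeds[s]);
    std::string err = invalid_reason(m);
    if (!err.empty()) stop("invalid seed: " + err);
    if (m.chg < 0) stop("seeds must be cations");
    CanonResult cr = canonical(m);
    Mol cm = relabel(m, cr.order);
    insert_node(st, cm, cr.code, 0, filter_mode, reject_mask, resonance_on, true);
  }
  std::vector<int> round_new_nodes, round_new_edges;
  round_new_nodes.push_back((int)st.mols.size());
  round_new_edges.push_back((int)st.edges.size());

  size_t frontier_begin = 0;
  int round = 0;
  while ((int)st.mols.size() > (int)frontier_begin &&
         (max_rounds < 0 || round < max_rounds)) {
    ++round;
    size_t frontier_end = st.mols.size();
    size_t edges_before = st.edges.size();
    for (size_t id = frontier_begin; id < frontier_end; ++id) {
      Mol reactant = st.mols[id]; // copy: store may reallocate
      std::vector<Cand> cands;
      expand(reactant, tv, shift_range, cands);
      for (auto& c : cands) {
        if (!invalid_reason(c.mol).empty()) continue;
        CanonResult cr = canonical(c.mol);
        if (cr.code == st.codes[id]) continue; // degenerate self edge
        Mol pm = relabel(c.mol, cr.order);
        int pid = insert_node(st, pm, cr.code, round, filter_mode, reject_mask,
                              resonance_on, false);
        if (pid >= 0) add_edge(st, (int)id, pid, c.type, c.a1, c.a2);
      }
      if (id % 64 == 0) Rcpp::checkUserInterrupt();
    }
    frontier_begin = frontier_end;
    round_new_nodes.push_back((int)(st.mols.size() - frontier_end));
    round_new_edges.push_back((int)(st.edges.size() - edges_before));
    if (st.mols.size() == frontier_end) break; // fixpoint
  }

  int nn = (int)st.mols.size();
  CharacterVector smiles(nn), skel(nn);
  IntegerVector rounds(nn), classes(nn);
  List mols(nn);
  for (int i = 0; i < nn; ++i) {
    smiles[i] = write_smiles(st.mols[i]);
    rounds[i] = st.rounds[i];
    classes[i] = st.classes[i];
    mols[i] = mol_to_r(st.mols[i]);
    Mol sk = skeleton_of(st.mols[i]);
    if (sk.n == 0) skel[i] = "";
    else {
      CanonResult cr = canonical(sk);
      skel[i] = write_smiles(relabel(sk, cr.order));
    }
  }
  int ne = (int)st.edges.size();
  IntegerMatrix em(ne, 5);
  for (int e = 0; e < ne; ++e) {
    em(e, 0) = st.edges[e][0] + 1; // from node id, 1-based
    em(e, 1) = st.edges[e][1] + 1; // to node id, 1-based
    em(e, 2) = st.edges[e][2];     // reaction type code
    em(e, 3) = st.edges[e][3] + 1; // participating carbons, 1-based,
    em(e, 4) = st.edges[e][4] + 1; // in the reactant's canonical labeling
  }

  return List::create(_["smiles"] = smiles,
                      _["round"] = rounds,
                      _["class"] = classes,
                      _["skeleton"] = skel,
                      _["mols"] = mols,
                      _["edges"] = em,
                      _["round_new_nodes"] = IntegerVector(round_new_nodes.begin(), round_new_nodes.end()),
                      _["round_new_edges"] = IntegerVector(round_new_edges.begin(), round_new_edges.end()));
}
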
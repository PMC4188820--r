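// Core engine: variant-path k-mer enumeration, entry replay (decoding recipes
// back into sequence), and seed-and-extend exact/approximate search over the
// reference + variant database.
//
// Conventions (shared with the R level):
//   * reference positions are 0-based and global (chromosomes concatenated);
//   * a variant is (kind, pos, del_len, ins):
//       kind 0 SNP  -> del_len 1, ins = alt character
//       kind 1 DEL  -> del_len >= 1, ins empty
//       kind 2 INS  -> del_len 0, ins non-empty (inserted before ref char pos)
//       kind 3 SV   -> del_len >= 1, ins non-empty
//     variants are sorted by (pos, input order) and indexed 0-based here;
//   * entry offsets are 1-based positions inside an insertion, 0 = the entry
//     starts on a reference character;
//   * a match record's `pre` is the 0-based global position of its first
//     reference character (equivalently the 1-based count of reference
//     characters strictly before it); for matches starting inside an
//     insertion `pre` is the anchor position and `offset` >= 1.

#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <map>
#include <string>
#include <vector>

using namespace Rcpp;

static const char NUC[6] = "ACGTN";

static inline int nuc_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2;
    case 'T': return 3; case 'N': return 4;
    default: return -1;
  }
}

// pattern char vs collection char: 'N' in a pattern never matches anything
static inline bool chmatch(char p, char t) { return p == t && p != 'N'; }

// ---------------------------------------------------------------------------
// context assembled from the R-side index pieces
// ---------------------------------------------------------------------------

struct Ctx {
  const uint8_t* ref;            // 4-bit packed, two codes per byte, high first
  int ref_len;
  std::vector<int> cstarts;      // chromosome starts, length n_chrom + 1

  std::vector<int> vpos, vdel, vkind;
  std::vector<std::string> vins;
  int nvar;

  std::vector<int> inv_res, inv_id;  // DEL/SV sorted by resulting position
  int max_del;

  char at(int i) const {
    uint8_t b = ref[i >> 1];
    return NUC[(i & 1) ? (b & 0x0F) : (b >> 4)];
  }
  int chrom_end(int pos) const {
    return *std::upper_bound(cstarts.begin(), cstarts.end() - 1, pos);
  }
  int chrom_begin(int pos) const {
    return *(std::upper_bound(cstarts.begin(), cstarts.end() - 1, pos) - 1);
  }
  int first_var_at_or_after(int pos) const {
    return (int)(std::lower_bound(vpos.begin(), vpos.end(), pos) - vpos.begin());
  }
  // deletions (DEL/SV) with pos < s < pos + del_len
  void spanning(int s, std::vector<int>& out) const {
    out.clear();
    if (inv_res.empty() || max_del <= 0) return;
    int lo = (int)(std::upper_bound(inv_res.begin(), inv_res.end(), s) - inv_res.begin());
    for (int i = lo; i < (int)inv_res.size() && inv_res[i] <= s + max_del; ++i) {
      int v = inv_id[i];
      if (vpos[v] < s) out.push_back(v);
    }
    std::sort(out.begin(), out.end());
  }
};

static Ctx make_ctx(RawVector ref, int ref_len, IntegerVector cstarts,
                    IntegerVector vpos, IntegerVector vdel, IntegerVector vkind,
                    CharacterVector vins, IntegerVector inv_res,
                    IntegerVector inv_id, int max_del) {
  Ctx c;
  c.ref = RAW(ref);
  c.ref_len = ref_len;
  c.cstarts.assign(cstarts.begin(), cstarts.end());
  c.vpos.assign(vpos.begin(), vpos.end());
  c.vdel.assign(vdel.begin(), vdel.end());
  c.vkind.assign(vkind.begin(), vkind.end());
  c.nvar = (int)vpos.size();
  c.vins.resize(c.nvar);
  for (int i = 0; i < c.nvar; ++i) c.vins[i] = std::string(vins[i]);
  c.inv_res.assign(inv_res.begin(), inv_res.end());
  c.inv_id.assign(inv_id.begin(), inv_id.end());
  c.max_del = max_del;
  return c;
}

// ---------------------------------------------------------------------------
// reference packing
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
RawVector cpp_pack_ref(std::string seq) {
  int n = (int)seq.size();
  RawVector out((n + 1) / 2);
  if (n) std::memset(RAW(out), 0, out.size());
  for (int i = 0; i < n; ++i) {
    int code = nuc_code(seq[i]);
    if (code < 0)
      stop("invalid character '%c' at position %d (A/C/G/T/N expected)", seq[i], i + 1);
    if (i & 1) RAW(out)[i >> 1] |= (uint8_t)code;
    else RAW(out)[i >> 1] |= (uint8_t)(code << 4);
  }
  return out;
}

// [[Rcpp::export]]
std::string cpp_unpack_ref(RawVector packed, int ref_len, int start, int n) {
  if (start < 0 || n < 0 || start + n > ref_len)
    stop("unpack range [%d, %d) out of bounds for reference of length %d",
         start, start + n, ref_len);
  std::string s(n, ' ');
  for (int i = 0; i < n; ++i) {
    int j = start + i;
    uint8_t b = RAW(packed)[j >> 1];
    s[i] = NUC[(j & 1) ? (b & 0x0F) : (b >> 4)];
  }
  return s;
}

// ---------------------------------------------------------------------------
// k-mer enumeration (index construction)
// ---------------------------------------------------------------------------

struct CandOut {
  std::vector<std::string> text;
  std::vector<int> pos_ref, offset;
  std::vector<int> ev_ptr, ev_len;
  std::vector<int> ev_vt, ev_flag;
  std::vector<int> sp_ptr, sp_len;
  std::vector<int> sp_vt;
  void push(int pr, int off, const std::string& t,
            const std::vector<std::pair<int, int> >& ev,
            const std::vector<int>& sp) {
    pos_ref.push_back(pr);
    offset.push_back(off);
    text.push_back(t);
    ev_ptr.push_back((int)ev_vt.size());
    ev_len.push_back((int)ev.size());
    for (size_t i = 0; i < ev.size(); ++i) {
      ev_vt.push_back(ev[i].first);
      ev_flag.push_back(ev[i].second);
    }
    sp_ptr.push_back((int)sp_vt.size());
    sp_len.push_back((int)sp.size());
    for (size_t i = 0; i < sp.size(); ++i) sp_vt.push_back(sp[i]);
  }
};

struct Enumerator {
  const Ctx& C;
  int k;
  long cap;
  long nodes;
  int start_s, start_off, cend;
  std::string text;
  std::vector<std::pair<int, int> > ev;
  std::vector<int> sp;
  CandOut& out;

  Enumerator(const Ctx& c, int k_, long cap_, CandOut& o)
      : C(c), k(k_), cap(cap_), nodes(0), start_s(0), start_off(0), cend(0), out(o) {}

  void emit() {
    if (text.empty() || text[0] == 'N') return;
    bool any = false;
    for (size_t i = 0; i < ev.size(); ++i)
      if (ev[i].second) { any = true; break; }
    if (!any) return;  // pure-reference path: represented by the category-0 entry
    out.push(start_s, start_off, text, ev, sp);
  }

  void walk(int pos, int vt) {
    if ((int)text.size() == k) { emit(); return; }
    if (++nodes > cap)
      stop("variant path explosion at reference position %d (cap %ld); raise path_cap or simplify input",
           start_s, cap);
    bool havev = vt < C.nvar && C.vpos[vt] < cend;
    if (!havev || C.vpos[vt] > pos) {
      if (pos >= cend) return;  // would run past the chromosome: drop short k-mer
      int nxt = havev ? std::min(C.vpos[vt], cend) : cend;
      int take = std::min(nxt - pos, k - (int)text.size());
      for (int i = 0; i < take; ++i) text.push_back(C.at(pos + i));
      if ((int)text.size() == k) emit();
      else walk(pos + take, vt);
      text.resize(text.size() - take);
      return;
    }
    int v = vt;
    if (C.vpos[v] == pos) {
      bool at_start = text.empty() && start_off == 0 && pos == start_s;
      if (at_start && C.vkind[v] != 0) {
        // the variant's characters (if any) fall before this k-mer start:
        // consume it silently; k-mers beginning inside its insertion are
        // enumerated separately as offset entries
        ev.push_back(std::make_pair(v, 1));
        walk(pos + C.vdel[v], vt + 1);
        ev.pop_back();
      } else {
        ev.push_back(std::make_pair(v, 1));
        int t = std::min((int)C.vins[v].size(), k - (int)text.size());
        text.append(C.vins[v], 0, t);
        if ((int)text.size() == k) emit();
        else walk(pos + C.vdel[v], vt + 1);
        text.resize(text.size() - t);
        ev.pop_back();
      }
      ev.push_back(std::make_pair(v, 0));
      walk(pos, vt + 1);
      ev.pop_back();
      return;
    }
    // C.vpos[v] < pos: variant sits inside a previously applied deletion;
    // only relevant if it deletes beyond it
    int nw = C.vpos[v] + C.vdel[v];
    if (nw > pos) {
      ev.push_back(std::make_pair(v, 1));
      int t = std::min((int)C.vins[v].size(), k - (int)text.size());
      text.append(C.vins[v], 0, t);
      if ((int)text.size() == k) emit();
      else walk(nw, vt + 1);
      text.resize(text.size() - t);
      ev.pop_back();
      ev.push_back(std::make_pair(v, 0));
      walk(pos, vt + 1);
      ev.pop_back();
    } else {
      walk(pos, vt + 1);
    }
  }
};

// [[Rcpp::export]]
List cpp_enumerate_kmers(RawVector ref, int ref_len, IntegerVector cstarts,
                         IntegerVector vpos, IntegerVector vdel,
                         IntegerVector vkind, CharacterVector vins,
                         IntegerVector inv_res, IntegerVector inv_id,
                         int max_del, int k, double path_cap) {
  Ctx C = make_ctx(ref, ref_len, cstarts, vpos, vdel, vkind, vins, inv_res,
                   inv_id, max_del);
  CandOut out;
  Enumerator E(C, k, (long)path_cap, out);
  std::vector<std::pair<int, int> > noev;

  for (size_t ci = 0; ci + 1 < C.cstarts.size(); ++ci) {
    int cb = C.cstarts[ci], ce = C.cstarts[ci + 1];
    for (int s = cb; s < ce; ++s) {
      // category-0 candidate (pure reference path); k-mers never cross a
      // chromosome boundary
      if (s + k <= ce && C.at(s) != 'N') {
        std::string t(k, ' ');
        for (int i = 0; i < k; ++i) t[i] = C.at(s + i);
        C.spanning(s, E.sp);
        out.push(s, 0, t, noev, E.sp);
      }
      // variant paths from this start (insertions may complete a k-mer even
      // within k characters of the chromosome end)
      int v0 = C.first_var_at_or_after(s);
      if (v0 < C.nvar && C.vpos[v0] < std::min(s + k, ce)) {
        E.start_s = s;
        E.start_off = 0;
        E.cend = ce;
        E.nodes = 0;
        C.spanning(s, E.sp);
        E.walk(s, v0);
      }
    }
    // k-mers starting inside insertions (INS/SV)
    for (int v = 0; v < C.nvar; ++v) {
      if (C.vpos[v] < cb || C.vpos[v] >= ce) continue;
      int ilen = (int)C.vins[v].size();
      if (C.vkind[v] != 2 && C.vkind[v] != 3) continue;  // SNP handled on ref path
      for (int j = 1; j <= ilen; ++j) {
        E.start_s = C.vpos[v];
        E.start_off = j;
        E.cend = ce;
        E.nodes = 0;
        C.spanning(C.vpos[v], E.sp);
        E.ev.push_back(std::make_pair(v, 1));
        int t = std::min(ilen - (j - 1), k);
        E.text.assign(C.vins[v], j - 1, t);
        if ((int)E.text.size() == k) E.emit();
        else E.walk(C.vpos[v] + C.vdel[v], v + 1);
        E.text.clear();
        E.ev.pop_back();
      }
    }
  }

  return List::create(
      _["text"] = wrap(out.text), _["pos_ref"] = wrap(out.pos_ref),
      _["offset"] = wrap(out.offset), _["ev_ptr"] = wrap(out.ev_ptr),
      _["ev_len"] = wrap(out.ev_len), _["ev_vt"] = wrap(out.ev_vt),
      _["ev_flag"] = wrap(out.ev_flag), _["sp_ptr"] = wrap(out.sp_ptr),
      _["sp_len"] = wrap(out.sp_len), _["sp_vt"] = wrap(out.sp_vt));
}

// ---------------------------------------------------------------------------
// entry replay: regenerate an entry's characters / decoding state
// ---------------------------------------------------------------------------

struct Subarr {
  std::vector<int> pos_ref, offset, ev_ptr, ev_len;
  const int* ev_vt;
  const int* ev_flag;
  std::vector<int> lut;
  int lut_width;
  int n() const { return (int)pos_ref.size(); }
};

static Subarr make_subarr(List s) {
  Subarr a;
  IntegerVector pr = s["pos_ref"], off = s["offset"], ep = s["ev_ptr"],
                el = s["ev_len"];
  a.pos_ref.assign(pr.begin(), pr.end());
  a.offset.assign(off.begin(), off.end());
  a.ev_ptr.assign(ep.begin(), ep.end());
  a.ev_len.assign(el.begin(), el.end());
  IntegerVector evv = s["ev_vt"], evf = s["ev_flag"];
  a.ev_vt = evv.size() ? INTEGER(evv) : NULL;
  a.ev_flag = evf.size() ? INTEGER(evf) : NULL;
  IntegerVector lut = s["lut"];
  a.lut.assign(lut.begin(), lut.end());
  a.lut_width = as<int>(s["lut_width"]);
  return a;
}

struct ReplayState {
  int pos, vt;       // next reference position / next variant index
  int inins_v;       // -1 if not inside an insertion
  int inins_off;     // 0-based index of next inserted char to emit
  int pre0, off0;    // projection of the first emitted character
  std::vector<std::pair<int, int> > flags;  // (variant, evidence) in encounter order
};

// replay `L` characters of an entry along its stored evidence path.
// buf (may be NULL) receives the characters.
static ReplayState replay_entry(const Ctx& C, int pos_ref, int offset,
                                const int* evv, const int* evf, int ev_len,
                                int L, char* buf) {
  ReplayState st;
  st.inins_v = -1;
  st.inins_off = 0;
  st.pre0 = -1;
  st.off0 = 0;
  int count = 0, ei = 0;
  int cend = C.chrom_end(pos_ref);
  int pos = pos_ref, vt;

  if (offset > 0) {
    int v = evv[0];  // entries inside an insertion always start with (v, 1)
    ei = 1;
    st.flags.push_back(std::make_pair(v, 1));
    st.pre0 = C.vpos[v];
    st.off0 = offset;
    const std::string& is = C.vins[v];
    int o = offset - 1;
    while (o < (int)is.size() && count < L) {
      if (buf) buf[count] = is[o];
      ++count; ++o;
    }
    if (count == L && o < (int)is.size()) {
      st.pos = C.vpos[v] + C.vdel[v];
      st.vt = v + 1;
      st.inins_v = v;
      st.inins_off = o;
      return st;
    }
    pos = C.vpos[v] + C.vdel[v];
    vt = v + 1;
  } else {
    vt = C.first_var_at_or_after(pos_ref);
  }

  while (count < L) {
    bool havev = vt < C.nvar && C.vpos[vt] < cend;
    if (!havev || C.vpos[vt] > pos) {
      if (pos >= cend) break;  // truncated by chromosome end
      int nxt = havev ? C.vpos[vt] : cend;
      int take = std::min(nxt - pos, L - count);
      if (st.pre0 < 0) { st.pre0 = pos; st.off0 = 0; }
      if (buf) for (int i = 0; i < take; ++i) buf[count + i] = C.at(pos + i);
      count += take;
      pos += take;
      continue;
    }
    int v = vt;
    bool flag = false;
    bool stored = (ei < ev_len && evv[ei] == v);
    if (stored) { flag = evf[ei] != 0; ++ei; }
    if (C.vpos[v] == pos) {
      bool at_start = (count == 0) && (offset == 0) && (pos == pos_ref);
      if (stored) st.flags.push_back(std::make_pair(v, flag ? 1 : 0));
      else st.flags.push_back(std::make_pair(v, 0));
      if (flag) {
        if (at_start && C.vkind[v] != 0) {
          pos += C.vdel[v];  // silently consumed: its characters precede the entry
          vt = v + 1;
        } else {
          const std::string& is = C.vins[v];
          int t = std::min((int)is.size(), L - count);
          if (t > 0 && st.pre0 < 0) {
            st.pre0 = C.vpos[v];
            st.off0 = (C.vkind[v] == 0) ? 0 : 1;  // SNP alt sits on the ref char
          }
          if (buf) for (int i = 0; i < t; ++i) buf[count + i] = is[i];
          count += t;
          if (count == L && t < (int)is.size()) {
            st.pos = C.vpos[v] + C.vdel[v];
            st.vt = v + 1;
            st.inins_v = v;
            st.inins_off = t;
            return st;
          }
          pos = C.vpos[v] + C.vdel[v];
          vt = v + 1;
        }
      } else {
        vt = v + 1;
      }
      continue;
    }
    // vpos[v] < pos: inside a previously applied deletion
    int nw = C.vpos[v] + C.vdel[v];
    if (nw > pos) {
      if (stored) st.flags.push_back(std::make_pair(v, flag ? 1 : 0));
      else st.flags.push_back(std::make_pair(v, 0));
      if (flag) {
        const std::string& is = C.vins[v];
        int t = std::min((int)is.size(), L - count);
        if (t > 0 && st.pre0 < 0) { st.pre0 = C.vpos[v]; st.off0 = 1; }
        if (buf) for (int i = 0; i < t; ++i) buf[count + i] = is[i];
        count += t;
        if (count == L && t < (int)is.size()) {
          st.pos = nw;
          st.vt = v + 1;
          st.inins_v = v;
          st.inins_off = t;
          return st;
        }
        pos = nw;
        vt = v + 1;
      } else {
        vt = v + 1;
      }
      continue;
    }
    vt = v + 1;  // wholly inside the deletion: pointless to track
  }
  st.pos = pos;
  st.vt = vt;
  if (count < L && buf) buf[count] = '\0';
  return st;
}

// [[Rcpp::export]]
CharacterVector cpp_entry_texts(RawVector ref, int ref_len, IntegerVector cstarts,
                                IntegerVector vpos, IntegerVector vdel,
                                IntegerVector vkind, CharacterVector vins,
                                IntegerVector inv_res, IntegerVector inv_id,
                                int max_del, List sub, int L) {
  Ctx C = make_ctx(ref, ref_len, cstarts, vpos, vdel, vkind, vins, inv_res,
                   inv_id, max_del);
  Subarr a = make_subarr(sub);
  CharacterVector out(a.n());
  std::vector<char> buf(L + 1);
  for (int i = 0; i < a.n(); ++i) {
    std::fill(buf.begin(), buf.end(), '\0');
    replay_entry(C, a.pos_ref[i], a.offset[i],
                 a.ev_vt ? a.ev_vt + a.ev_ptr[i] : NULL,
                 a.ev_flag ? a.ev_flag + a.ev_ptr[i] : NULL, a.ev_len[i], L,
                 buf.data());
    out[i] = std::string(buf.data());
  }
  return out;
}

// projection of the first character of each entry (pre, offset)
// [[Rcpp::export]]
List cpp_entry_projection(RawVector ref, int ref_len, IntegerVector cstarts,
                          IntegerVector vpos, IntegerVector vdel,
                          IntegerVector vkind, CharacterVector vins,
                          IntegerVector inv_res, IntegerVector inv_id,
                          int max_del, List sub) {
  Ctx C = make_ctx(ref, ref_len, cstarts, vpos, vdel, vkind, vins, inv_res,
                   inv_id, max_del);
  Subarr a = make_subarr(sub);
  IntegerVector pre(a.n()), off(a.n());
  for (int i = 0; i < a.n(); ++i) {
    ReplayState st = replay_entry(C, a.pos_ref[i], a.offset[i],
                                  a.ev_vt ? a.ev_vt + a.ev_ptr[i] : NULL,
                                  a.ev_flag ? a.ev_flag + a.ev_ptr[i] : NULL,
                                  a.ev_len[i], 1, NULL);
    pre[i] = st.pre0;
    off[i] = st.off0;
  }
  return List::create(_["pre"] = pre, _["offset"] = off);
}

// spec-surface partial decode: state after decoding p characters of an entry,
// evidence list prefixed with the spanning deletions of the entry anchor
// [[Rcpp::export]]
List cpp_part_decode(RawVector ref, int ref_len, IntegerVector cstarts,
                     IntegerVector vpos, IntegerVector vdel,
                     IntegerVector vkind, CharacterVector vins,
                     IntegerVector inv_res, IntegerVector inv_id, int max_del,
                     int pos_ref, int offset, IntegerVector ev_vt,
                     IntegerVector ev_flag, int p) {
  Ctx C = make_ctx(ref, ref_len, cstarts, vpos, vdel, vkind, vins, inv_res,
                   inv_id, max_del);
  std::vector<int> sp;
  C.spanning(pos_ref, sp);
  std::vector<char> buf(p + 1, '\0');
  ReplayState st = replay_entry(C, pos_ref, offset,
                                ev_vt.size() ? INTEGER(ev_vt) : NULL,
                                ev_flag.size() ? INTEGER(ev_flag) : NULL,
                                (int)ev_vt.size(), p, buf.data());
  std::vector<int> vl, el;
  for (size_t i = 0; i < sp.size(); ++i) { vl.push_back(sp[i]); el.push_back(0); }
  for (size_t i = 0; i < st.flags.size(); ++i) {
    vl.push_back(st.flags[i].first);
    el.push_back(st.flags[i].second);
  }
  return List::create(_["vtList"] = wrap(vl), _["evList"] = wrap(el),
                      _["pos_curr"] = st.pos, _["vt_curr"] = st.vt,
                      _["in_ins"] = st.inins_v, _["in_ins_off"] = st.inins_off,
                      _["text"] = std::string(buf.data()), _["pre"] = st.pre0,
                      _["offset_out"] = st.off0);
}

// ---------------------------------------------------------------------------
// subarray interval lookup (LUT-narrowed binary search on reconstructed text)
// ---------------------------------------------------------------------------

// compare an entry's first |seed| characters with the seed
static int entry_cmp(const Ctx& C, const Subarr& a, int i, const std::string& seed) {
  std::vector<char> buf(seed.size() + 1, '\0');
  replay_entry(C, a.pos_ref[i], a.offset[i],
               a.ev_vt ? a.ev_vt + a.ev_ptr[i] : NULL,
               a.ev_flag ? a.ev_flag + a.ev_ptr[i] : NULL, a.ev_len[i],
               (int)seed.size(), buf.data());
  for (size_t j = 0; j < seed.size(); ++j) {
    if (buf[j] == '\0') return -1;  // truncated entry text sorts low
    if (buf[j] != seed[j]) return buf[j] < seed[j] ? -1 : 1;
  }
  return 0;
}

static std::pair<int, int> interval_lookup_c(const Ctx& C, const Subarr& a,
                                             const std::string& seed) {
  int lo = 0, hi = a.n();
  int w = a.lut_width;
  if (w > 0 && (int)seed.size() >= w && !a.lut.empty()) {
    long p = 0;
    bool ok = true;
    for (int j = 0; j < w; ++j) {
      int c = nuc_code(seed[j]);
      if (c < 0 || c > 3) { ok = false; break; }
      p = p * 4 + c;
    }
    if (ok) { lo = a.lut[p]; hi = a.lut[p + 1]; }
  }
  // lower bound: first entry with prefix >= seed
  int l = lo, h = hi;
  while (l < h) {
    int m = l + (h - l) / 2;
    if (entry_cmp(C, a, m, seed) < 0) l = m + 1;
    else h = m;
  }
  int first = l;
  // upper bound: first entry with prefix > seed
  l = first; h = hi;
  while (l < h) {
    int m = l + (h - l) / 2;
    if (entry_cmp(C, a, m, seed) <= 0) l = m + 1;
    else h = m;
  }
  return std::make_pair(first, l);
}

// [[Rcpp::export]]
IntegerVector cpp_interval_lookup(RawVector ref, int ref_len,
                                  IntegerVector cstarts, IntegerVector vpos,
                                  IntegerVector vdel, IntegerVector vkind,
                                  CharacterVector vins, IntegerVector inv_res,
                                  IntegerVector inv_id, int max_del, List sub,
                                  std::string seed) {
  Ctx C = make_ctx(ref, ref_len, cstarts, vpos, vdel, vkind, vins, inv_res,
                   inv_id, max_del);
  Subarr a = make_subarr(sub);
  std::pair<int, int> iv = interval_lookup_c(C, a, seed);
  return IntegerVector::create(iv.first, iv.second);
}

// ---------------------------------------------------------------------------
// presence filter support: haplotype sets from evidence lists
// ---------------------------------------------------------------------------

// keep[i] = TRUE iff some haplotype carries exactly the flagged combination,
// with spanning deletions (and, for empty evidence, every variant inside
// [pos_ref, pos_ref + k)) required absent
// [[Rcpp::export]]
LogicalVector cpp_presence_keep(LogicalMatrix occ, IntegerVector vpos,
                                IntegerVector pos_ref, IntegerVector offset,
                                IntegerVector ev_ptr, IntegerVector ev_len,
                                IntegerVector ev_vt, IntegerVector ev_flag,
                                IntegerVector sp_ptr, IntegerVector sp_len,
                                IntegerVector sp_vt, int k) {
  int ncand = (int)pos_ref.size();
  int nh = occ.ncol();
  int nvar = occ.nrow();
  LogicalVector keep(ncand);
  std::vector<uint8_t> R(nh);
  std::vector<int> pv(vpos.begin(), vpos.end());
  for (int i = 0; i < ncand; ++i) {
    std::fill(R.begin(), R.end(), 1);
    for (int j = 0; j < sp_len[i]; ++j) {
      int v = sp_vt[sp_ptr[i] + j];
      for (int h = 0; h < nh; ++h) if (occ(v, h)) R[h] = 0;
    }
    if (ev_len[i] == 0) {
      // category-0: every variant starting inside the window must be absent
      int lo = (int)(std::lower_bound(pv.begin(), pv.end(), pos_ref[i]) - pv.begin());
      for (int v = lo; v < nvar && pv[v] < pos_ref[i] + k; ++v)
        for (int h = 0; h < nh; ++h) if (occ(v, h)) R[h] = 0;
    } else {
      for (int j = 0; j < ev_len[i]; ++j) {
        int v = ev_vt[ev_ptr[i] + j];
        int f = ev_flag[ev_ptr[i] + j];
        for (int h = 0; h < nh; ++h) {
          if (f) { if (!occ(v, h)) R[h] = 0; }
          else   { if (occ(v, h))  R[h] = 0; }
        }
      }
    }
    bool any = false;
    for (int h = 0; h < nh; ++h) if (R[h]) { any = true; break; }
    keep[i] = any;
  }
  return keep;
}

// ---------------------------------------------------------------------------
// search
// ---------------------------------------------------------------------------

struct Rec {
  int pre, off, mism;
  std::vector<std::pair<int, int> > ev;
  std::vector<uint8_t> haps;
};

struct Searcher {
  const Ctx& C;
  const LogicalMatrix& occ;
  int nh;
  std::string P;
  int m, q, k, d;
  long node_cap, nodes;
  int seg_lo, seg_hi;  // mismatches forbidden inside [seg_lo, seg_hi)
  int st;              // pattern index where the current seed starts
  int cbeg, cend;      // chromosome bounds of the current seed entry
  std::vector<int> S;  // variants present on the current path
  std::map<std::string, Rec> found;

  Searcher(const Ctx& c, const LogicalMatrix& o)
      : C(c), occ(o), nh(o.ncol()), m(0), q(0), k(0), d(1), node_cap(0),
        nodes(0), seg_lo(0), seg_hi(0), st(0), cbeg(0), cend(0) {}

  bool allow_mm(int ch, int used) const {
    return used < q && (ch < seg_lo || ch >= seg_hi);
  }

  void bump() {
    if (++nodes > node_cap)
      stop("seed extension exceeded the node cap (%ld); raise node_cap", node_cap);
  }

  // --- canonical record production -------------------------------------

  void emit_record(int pre0, int off0, int mism,
                   std::vector<std::pair<int, int> >& ev) {
    std::sort(ev.begin(), ev.end());
    std::vector<uint8_t> R(nh, 1);
    for (size_t i = 0; i < ev.size(); ++i) {
      int v = ev[i].first;
      bool f = ev[i].second != 0;
      for (int h = 0; h < nh; ++h) {
        if (f) { if (!occ(v, h)) R[h] = 0; }
        else   { if (occ(v, h))  R[h] = 0; }
      }
    }
    bool any = false;
    for (int h = 0; h < nh; ++h) if (R[h]) { any = true; break; }
    if (!any) return;
    std::string key;
    key.reserve(16 + ev.size() * 8);
    key += std::to_string(pre0); key += ':'; key += std::to_string(off0);
    for (size_t i = 0; i < ev.size(); ++i) {
      key += ';'; key += std::to_string(ev[i].first);
      key += ev[i].second ? '+' : '-';
    }
    std::map<std::string, Rec>::iterator it = found.find(key);
    if (it != found.end()) {
      if (mism < it->second.mism) it->second.mism = mism;
      return;
    }
    Rec r;
    r.pre = pre0; r.off = off0; r.mism = mism; r.ev = ev; r.haps = R;
    found[key] = r;
  }

  bool inS(int v) const {
    return std::find(S.begin(), S.end(), v) != S.end();
  }

  // canonical forward verification: walk the full pattern from the match
  // start along the present-set, rebuilding the evidence list exactly as the
  // dense-mode decoder would
  void verify(bool ins_start, int sx, int soff) {
    std::vector<std::pair<int, int> > ev;
    int pre0 = -1, off0 = 0;
    int count = 0, mism = 0;
    int pos, vt;
    if (ins_start) {
      int v = sx;
      ev.push_back(std::make_pair(v, 1));
      pre0 = C.vpos[v]; off0 = soff;
      const std::string& is = C.vins[v];
      for (int o = soff - 1; o < (int)is.size() && count < m; ++o, ++count)
        if (!chmatch(P[count], is[o]) && ++mism > q) return;
      pos = C.vpos[v] + C.vdel[v];
      vt = v + 1;
    } else {
      pos = sx;
      vt = C.first_var_at_or_after(sx);
    }
    while (count < m) {
      bool havev = vt < C.nvar && C.vpos[vt] < cend;
      if (!havev || C.vpos[vt] > pos) {
        if (pos >= cend) return;
        int nxt = havev ? C.vpos[vt] : cend;
        int take = std::min(nxt - pos, m - count);
        if (pre0 < 0) { pre0 = pos; off0 = 0; }
        for (int i = 0; i < take; ++i)
          if (!chmatch(P[count + i], C.at(pos + i)) && ++mism > q) return;
        count += take; pos += take;
        continue;
      }
      int v = vt;
      if (C.vpos[v] == pos) {
        if (count == 0 && C.vkind[v] != 0) {
          if (C.vdel[v] == 0) {
            // insertion attached before the start: cannot change the window
            if (inS(v)) { pos += C.vdel[v]; }
            vt = v + 1;
          } else if (inS(v)) {
            pos += C.vdel[v];  // window starts beyond this deletion
            vt = v + 1;
          } else {
            ev.push_back(std::make_pair(v, 0));  // would delete the start char
            vt = v + 1;
          }
          continue;
        }
        if (inS(v)) {
          ev.push_back(std::make_pair(v, 1));
          const std::string& is = C.vins[v];
          int t = std::min((int)is.size(), m - count);
          if (t > 0 && pre0 < 0) {
            pre0 = C.vpos[v];
            off0 = (C.vkind[v] == 0) ? 0 : 1;
          }
          for (int i = 0; i < t; ++i)
            if (!chmatch(P[count + i], is[i]) && ++mism > q) return;
          count += t;
          pos = C.vpos[v] + C.vdel[v];
          vt = v + 1;
        } else {
          ev.push_back(std::make_pair(v, 0));
          vt = v + 1;
        }
        continue;
      }
      int nw = C.vpos[v] + C.vdel[v];
      if (nw > pos) {
        if (inS(v)) {
          ev.push_back(std::make_pair(v, 1));
          const std::string& is = C.vins[v];
          int t = std::min((int)is.size(), m - count);
          if (t > 0 && pre0 < 0) { pre0 = C.vpos[v]; off0 = 1; }
          for (int i = 0; i < t; ++i)
            if (!chmatch(P[count + i], is[i]) && ++mism > q) return;
          count += t;
          pos = nw;
          vt = v + 1;
        } else {
          ev.push_back(std::make_pair(v, 0));
          vt = v + 1;
        }
        continue;
      }
      vt = v + 1;
    }
    // deletions spanning the first character must be absent
    int a0 = pre0;
    std::vector<int> sp;
    C.spanning(a0, sp);
    for (size_t i = 0; i < sp.size(); ++i) {
      bool seen = false;
      for (size_t j = 0; j < ev.size(); ++j)
        if (ev[j].first == sp[i]) { seen = true; break; }
      if (!seen) ev.push_back(std::make_pair(sp[i], 0));
    }
    emit_record(pre0, off0, mism, ev);
  }

  // --- leftward extension ------------------------------------------------

  // f0_*: projection of the seed entry's first character, used when no left
  // characters remain
  void left_done(bool ins_state, int v_or_b, int oo) {
    if (ins_state) verify(true, v_or_b, oo);
    else verify(false, v_or_b, 0);
  }

  // i: index of next pattern character to emit (descending); boundary state
  void left_ref(int i, int b, int used);
  void left_ins(int i, int v, int oo, int used);

  // --- rightward extension ----------------------------------------------

  // after the right side completes: run the left side (or verify directly)
  bool f0_ins;  // seed entry first-char projection
  int f0_x, f0_off;

  void right_done(int used) {
    if (st == 0) {
      if (f0_ins) verify(true, f0_x, f0_off);
      else verify(false, f0_x, 0);
      return;
    }
    if (f0_ins) left_ins(st - 1, f0_x, f0_off - 1, used);
    else left_ref(st - 1, f0_x, used);
  }

  void right(int ch, int pos, int vt, int used);
  bool right_ins(int v, int from_off, int ch, int nxt_pos, int used);
};

void Searcher::right(int ch, int pos, int vt, int used) {
  bump();
  while (true) {
    if (ch == m) { right_done(used); return; }
    bool havev = vt < C.nvar && C.vpos[vt] < cend;
    if (!havev || C.vpos[vt] > pos) {
      if (pos >= cend) return;
      char c = C.at(pos);
      if (!chmatch(P[ch], c)) {
        if (!allow_mm(ch, used)) return;
        ++used;
      }
      ++ch; ++pos;
      continue;
    }
    int v = vt;
    if (C.vpos[v] == pos) {
      S.push_back(v);
      right_ins(v, 0, ch, C.vpos[v] + C.vdel[v], used);
      S.pop_back();
      vt = v + 1;  // absent branch
      continue;
    }
    int nw = C.vpos[v] + C.vdel[v];
    if (nw > pos) {
      S.push_back(v);
      right_ins(v, 0, ch, nw, used);
      S.pop_back();
    }
    vt = v + 1;
    continue;
  }
}

// emit the inserted characters of v (from from_off), then continue right
bool Searcher::right_ins(int v, int from_off, int ch, int nxt_pos, int used) {
  bump();
  const std::string& is = C.vins[v];
  for (int o = from_off; o < (int)is.size(); ++o) {
    if (ch == m) { right_done(used); return true; }
    if (!chmatch(P[ch], is[o])) {
      if (!allow_mm(ch, used)) return false;
      ++used;
    }
    ++ch;
  }
  if (ch == m) { right_done(used); return true; }
  right(ch, nxt_pos, v + 1, used);
  return true;
}

void Searcher::left_ref(int i, int b, int used) {
  bump();
  if (i < 0) { left_done(false, b, 0); return; }
  // 1. plain reference character
  if (b > cbeg) {
    char c = C.at(b - 1);
    bool ok = chmatch(P[i], c);
    if (ok || allow_mm(i, used)) left_ref(i - 1, b - 1, used + (ok ? 0 : 1));
  }
  // 2. SNP whose alternative sits at b-1
  if (b > cbeg) {
    int lo = C.first_var_at_or_after(b - 1);
    for (int v = lo; v < C.nvar && C.vpos[v] == b - 1; ++v) {
      if (C.vkind[v] != 0) continue;
      char c = C.vins[v][0];
      bool ok = chmatch(P[i], c);
      if (ok || allow_mm(i, used)) {
        S.push_back(v);
        left_ref(i - 1, b - 1, used + (ok ? 0 : 1));
        S.pop_back();
      }
    }
  }
  // 3. insertion attached at b: its characters precede char b
  {
    int lo = C.first_var_at_or_after(b);
    for (int v = lo; v < C.nvar && C.vpos[v] == b; ++v) {
      if (C.vkind[v] != 2) continue;
      S.push_back(v);
      left_ins(i, v, (int)C.vins[v].size(), used);
      S.pop_back();
    }
  }
  // 4. DEL/SV whose resulting position is b
  {
    int lo = (int)(std::lower_bound(C.inv_res.begin(), C.inv_res.end(), b) -
                   C.inv_res.begin());
    for (int j = lo; j < (int)C.inv_res.size() && C.inv_res[j] == b; ++j) {
      int v = C.inv_id[j];
      if (C.vpos[v] < cbeg) continue;
      S.push_back(v);
      if (C.vins[v].empty()) left_ref(i, C.vpos[v], used);
      else left_ins(i, v, (int)C.vins[v].size(), used);
      S.pop_back();
    }
  }
}

void Searcher::left_ins(int i, int v, int oo, int used) {
  bump();
  while (oo > 0) {
    if (i < 0) { left_done(true, v, oo + 1); return; }
    char c = C.vins[v][oo - 1];
    if (!chmatch(P[i], c)) {
      if (!allow_mm(i, used)) return;
      ++used;
    }
    --i; --oo;
  }
  if (i < 0) { left_done(true, v, 1); return; }
  left_ref(i, C.vpos[v], used);
}

// [[Rcpp::export]]
List cpp_search_batch(RawVector ref, int ref_len, IntegerVector cstarts,
                      IntegerVector vpos, IntegerVector vdel,
                      IntegerVector vkind, CharacterVector vins,
                      IntegerVector inv_res, IntegerVector inv_id, int max_del,
                      List kma, LogicalMatrix occ, CharacterVector patterns,
                      int q, int d, int k, double node_cap) {
  Ctx C = make_ctx(ref, ref_len, cstarts, vpos, vdel, vkind, vins, inv_res,
                   inv_id, max_del);
  std::vector<Subarr> subs;
  for (int i = 0; i < 4; ++i) subs.push_back(make_subarr(kma[i]));

  std::vector<int> out_query, out_pre, out_off, out_mism;
  std::vector<int> out_evptr, out_evlen, out_evvt, out_evflag;
  std::vector<uint8_t> out_haps;
  int nh = occ.ncol();

  for (int pi = 0; pi < patterns.size(); ++pi) {
    Searcher Se(C, occ);
    Se.P = std::string(patterns[pi]);
    Se.m = (int)Se.P.size();
    Se.q = q;
    Se.k = k;
    Se.d = d;
    Se.node_cap = (long)node_cap;
    if (Se.m < 1) continue;

    int nseg = q + 1;
    int L = Se.m / nseg;
    if (L < 1)
      stop("pattern %d is too short for %d mismatches (pigeonhole split impossible)",
           pi + 1, q);

    for (int seg = 0; seg < nseg; ++seg) {
      int lo = (q == 0) ? 0 : seg * L;
      int hi = (q == 0) ? Se.m : lo + L;
      for (int jj = 0; jj < d; ++jj) {
        int stp = lo + jj;
        if (stp >= hi) break;
        int p = std::min(k, hi - stp);
        if (p < 1) break;
        std::string seed = Se.P.substr(stp, p);
        bool okseed = true;
        for (size_t ci = 0; ci < seed.size(); ++ci) {
          int cc = nuc_code(seed[ci]);
          if (cc < 0 || cc > 3) { okseed = false; break; }
        }
        if (!okseed) continue;
        Se.seg_lo = lo;
        Se.seg_hi = hi;
        Se.st = stp;
        for (int si = 0; si < 4; ++si) {
          const Subarr& a = subs[si];
          std::pair<int, int> iv = interval_lookup_c(C, a, seed);
          for (int e = iv.first; e < iv.second; ++e) {
            Se.nodes = 0;
            ReplayState rst = replay_entry(
                C, a.pos_ref[e], a.offset[e],
                a.ev_vt ? a.ev_vt + a.ev_ptr[e] : NULL,
                a.ev_flag ? a.ev_flag + a.ev_ptr[e] : NULL, a.ev_len[e], p,
                NULL);
            Se.cbeg = C.chrom_begin(a.pos_ref[e]);
            Se.cend = C.chrom_end(a.pos_ref[e]);
            Se.f0_ins = rst.off0 > 0;
            Se.f0_x = Se.f0_ins ? /*variant id*/ -1 : rst.pre0;
            Se.f0_off = rst.off0;
            Se.S.clear();
            for (size_t fi = 0; fi < rst.flags.size(); ++fi)
              if (rst.flags[fi].second) Se.S.push_back(rst.flags[fi].first);
            if (Se.f0_ins) {
              // the first character is inside the insertion of the entry's
              // first evidence variant
              Se.f0_x = a.ev_vt[a.ev_ptr[e]];
            }
            if (rst.inins_v >= 0)
              Se.right_ins(rst.inins_v, rst.inins_off, stp + p, rst.pos, 0);
            else
              Se.right(stp + p, rst.pos, rst.vt, 0);
          }
        }
      }
    }

    for (std::map<std::string, Rec>::iterator it = Se.found.begin();
         it != Se.found.end(); ++it) {
      const Rec& r = it->second;
      out_query.push_back(pi + 1);
      out_pre.push_back(r.pre);
      out_off.push_back(r.off);
      out_mism.push_back(r.mism);
      out_evptr.push_back((int)out_evvt.size());
      out_evlen.push_back((int)r.ev.size());
      for (size_t i = 0; i < r.ev.size(); ++i) {
        out_evvt.push_back(r.ev[i].first);
        out_evflag.push_back(r.ev[i].second);
      }
      for (int h = 0; h < nh; ++h) out_haps.push_back(r.haps[h]);
    }
  }

  int nrec = (int)out_query.size();
  LogicalMatrix hm(nrec, nh);
  for (int i = 0; i < nrec; ++i)
    for (int h = 0; h < nh; ++h) hm(i, h) = out_haps[(size_t)i * nh + h] != 0;
  return List::create(
      _["query"] = wrap(out_query), _["pre"] = wrap(out_pre),
      _["offset"] = wrap(out_off), _["mismatches"] = wrap(out_mism),
      _["ev_ptr"] = wrap(out_evptr), _["ev_len"] = wrap(out_evlen),
      _["ev_vt"] = wrap(out_evvt), _["ev_flag"] = wrap(out_evflag),
      _["haps"] = hm);
}

// ---------------------------------------------------------------------------
// small utility: crc-style checksum for the index container
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_checksum(RawVector x) {
  // Adler-32
  uint32_t a = 1, b = 0;
  const uint8_t* p = RAW(x);
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    a = (a + p[i]) % 65521u;
    b = (b + a) % 65521u;
  }
  return (double)((b << 16) | a);
}
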
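#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// Di-base color code with A=0,C=1,G=2,T=3 is XOR of the two base codes:
// identical pair -> 0, {A,C}/{G,T} -> 1, {A,G}/{C,T} -> 2, {A,T}/{C,G} -> 3.

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}
static const char BASE_CHR[4] = {'A', 'C', 'G', 'T'};

// [[Rcpp::export]]
CharacterVector cpp_encode_colors(CharacterVector seqs, IntegerVector primer) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string col(s.size(), '0');
    int prev = primer[i];
    for (size_t j = 0; j < s.size(); ++j) {
      int b = base_code(s[j]);
      if (b < 0) stop("invalid base '%s' at position %d of sequence %d",
                      std::string(1, s[j]).c_str(), (int)j + 1, i + 1);
      col[j] = (char)('0' + (prev ^ b));
      prev = b;
    }
    out[i] = col;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode_colors(CharacterVector cols, IntegerVector primer) {
  int n = cols.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string c = as<std::string>(cols[i]);
    std::string s(c.size(), 'A');
    int prev = primer[i];
    for (size_t j = 0; j < c.size(); ++j) {
      int d = c[j] - '0';
      if (d < 0 || d > 3) stop("invalid color '%s' at position %d of read %d",
                               std::string(1, c[j]).c_str(), (int)j + 1, i + 1);
      prev = prev ^ d;
      s[j] = BASE_CHR[prev];
    }
    out[i] = s;
  }
  return out;
}

namespace {

const int SEED_K = 6;
const int NKEY = 1 << (2 * SEED_K);  // 4^6

struct Hit {
  int mm, rank, pos, strand, refidx;  // pos: 1-based forward-strand start
  bool operator<(const Hit& o) const {
    if (mm != o.mm) return mm < o.mm;
    if (rank != o.rank) return rank < o.rank;
    if (pos != o.pos) return pos < o.pos;
    return strand < o.strand;  // 0 (+) before 1 (-)
  }
};

// One searchable strand of a reference: base codes, and (for color-space
// queries) the derived color codes between adjacent bases.
struct StrandSeq {
  std::vector<uint8_t> b;    // base codes 0..3
  std::vector<uint8_t> col;  // b[i] ^ b[i+1], length L-1
  int refidx;                // 0-based reference index
  int strand;                // 0 forward, 1 reverse-complement
  int L;
};

}  // namespace

// Align a library of reads against one set of reference sequences using the
// full-length-then-trim ladder. Reads are compared in color space (against
// the color-encoded reference, first color checked against the primer
// transition) or directly in nucleotide space. Candidate placements come
// from a 6-mer pigeonhole index (a read with <= 2 mismatches over >= 19
// symbols always has one clean third, whose leading 6-mer is indexed);
// each candidate is verified by exhaustive mismatch counting.
//
// reads: color digit strings (colorspace=true) or base strings.
// lengths: descending ladder of aligned lengths, first entry = untrimmed.
// Returns per-placement vectors plus a per-read status:
//   0 aligned, 1 unaligned, 2 too short.
// [[Rcpp::export]]
List cpp_align_library(CharacterVector ref_seqs, IntegerVector ref_rank,
                       CharacterVector reads, IntegerVector primers,
                       bool colorspace, IntegerVector lengths,
                       int min_len, int max_mm, int kmax) {
  int nref = ref_seqs.size();
  std::vector<StrandSeq> seqs;
  seqs.reserve(2 * nref);
  for (int i = 0; i < nref; ++i) {
    std::string s = as<std::string>(ref_seqs[i]);
    int L = s.size();
    StrandSeq fw, rv;
    fw.refidx = rv.refidx = i;
    fw.strand = 0; rv.strand = 1;
    fw.L = rv.L = L;
    fw.b.resize(L); rv.b.resize(L);
    for (int j = 0; j < L; ++j) {
      int bc = base_code(s[j]);
      if (bc < 0) stop("invalid base in reference %d", i + 1);
      fw.b[j] = bc;
      rv.b[L - 1 - j] = 3 - bc;  // complement: A<->T (0<->3), C<->G (1<->2)
    }
    if (colorspace) {
      if (L > 1) {
        fw.col.resize(L - 1); rv.col.resize(L - 1);
        for (int j = 0; j + 1 < L; ++j) {
          fw.col[j] = fw.b[j] ^ fw.b[j + 1];
          rv.col[j] = rv.b[j] ^ rv.b[j + 1];
        }
      }
    }
    seqs.push_back(fw);
    seqs.push_back(rv);
  }

  // CSR 6-mer index over the comparison arrays (colors or bases)
  std::vector<int> bucket_n(NKEY + 1, 0);
  auto arr_of = [&](const StrandSeq& q) -> const std::vector<uint8_t>& {
    return colorspace ? q.col : q.b;
  };
  for (size_t j = 0; j < seqs.size(); ++j) {
    const std::vector<uint8_t>& a = arr_of(seqs[j]);
    if ((int)a.size() < SEED_K) continue;
    int key = 0;
    for (int t = 0; t < SEED_K; ++t) key = (key << 2) | a[t];
    bucket_n[key + 1]++;
    for (size_t p = SEED_K; p < a.size(); ++p) {
      key = ((key << 2) | a[p]) & (NKEY - 1);
      bucket_n[key + 1]++;
    }
  }
  for (int k = 0; k < NKEY; ++k) bucket_n[k + 1] += bucket_n[k];
  int nentry = bucket_n[NKEY];
  std::vector<int> ent_seq(nentry), ent_pos(nentry);
  {
    std::vector<int> fill(bucket_n.begin(), bucket_n.end() - 1);
    for (size_t j = 0; j < seqs.size(); ++j) {
      const std::vector<uint8_t>& a = arr_of(seqs[j]);
      if ((int)a.size() < SEED_K) continue;
      int key = 0;
      for (int t = 0; t < SEED_K; ++t) key = (key << 2) | a[t];
      ent_seq[fill[key]] = j; ent_pos[fill[key]] = 0; fill[key]++;
      for (size_t p = SEED_K; p < a.size(); ++p) {
        key = ((key << 2) | a[p]) & (NKEY - 1);
        int at = fill[key]++;
        ent_seq[at] = j; ent_pos[at] = p - SEED_K + 1;
      }
    }
  }

  int nreads = reads.size();
  IntegerVector status(nreads);
  std::vector<int> o_read, o_ref, o_pos, o_strand, o_len, o_mm, o_step;

  std::vector<int> ladder;
  std::vector<std::pair<int,int>> cand;
  std::vector<Hit> hits;

  for (int r = 0; r < nreads; ++r) {
    std::string rs = as<std::string>(reads[r]);
    int n = rs.size();
    std::vector<uint8_t> q(n);
    for (int j = 0; j < n; ++j) {
      int v = colorspace ? (rs[j] - '0') : base_code(rs[j]);
      if (colorspace && (v < 0 || v > 3)) stop("invalid color in read %d", r + 1);
      if (!colorspace && v < 0) stop("invalid base in read %d", r + 1);
      q[j] = v;
    }
    int prim = colorspace ? primers[r] : 0;

    if (n < min_len) { status[r] = 2; continue; }
    ladder.clear();
    if (lengths.size() > 0 && n == lengths[0]) {
      for (int t = 0; t < lengths.size(); ++t) ladder.push_back(lengths[t]);
    } else {
      ladder.push_back(n);
      for (int t = 0; t < lengths.size(); ++t)
        if (lengths[t] < n) ladder.push_back(lengths[t]);
    }

    bool placed = false;
    for (size_t step = 0; step < ladder.size() && !placed; ++step) {
      int m = ladder[step];
      // seed offsets: max_mm+1 segments of the diagonal-constrained
      // positions; at least one segment is mismatch-free, so its leading
      // 6-mer is an exact index hit
      int first = colorspace ? 1 : 0;    // read color 0 has no reference color
      int total = m - first;
      int nseg = max_mm + 1;
      int part = total / nseg;
      cand.clear();
      if (part >= SEED_K) {
        for (int si = 0; si < nseg; ++si) {
          int o = first + si * part;
          if (o + SEED_K > m) continue;
          int key = 0;
          for (int t = 0; t < SEED_K; ++t) key = (key << 2) | q[o + t];
          for (int e = bucket_n[key]; e < bucket_n[key + 1]; ++e) {
            int j = ent_seq[e];
            int qstart = colorspace ? (ent_pos[e] - (o - 1)) : (ent_pos[e] - o);
            if (qstart < 0 || qstart + m > seqs[j].L) continue;
            cand.push_back(std::make_pair(j, qstart));
          }
        }
        std::sort(cand.begin(), cand.end());
        cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      } else {
        // segments too short to seed reliably: exhaustive candidate list
        for (size_t j = 0; j < seqs.size(); ++j)
          for (int qs = 0; qs + m <= seqs[j].L; ++qs)
            cand.push_back(std::make_pair((int)j, qs));
      }

      hits.clear();
      for (size_t c = 0; c < cand.size(); ++c) {
        const StrandSeq& S = seqs[cand[c].first];
        int qs = cand[c].second;
        int mm = 0;
        if (colorspace) {
          if (q[0] != (prim ^ S.b[qs])) mm++;
          for (int i = 1; i < m && mm <= max_mm; ++i)
            if (q[i] != S.col[qs + i - 1]) mm++;
        } else {
          for (int i = 0; i < m && mm <= max_mm; ++i)
            if (q[i] != S.b[qs + i]) mm++;
        }
        if (mm > max_mm) continue;
        Hit h;
        h.mm = mm;
        h.refidx = S.refidx;
        h.rank = ref_rank[S.refidx];
        h.strand = S.strand;
        h.pos = S.strand == 0 ? qs + 1 : S.L - qs - m + 1;
        hits.push_back(h);
      }
      if (!hits.empty()) {
        std::sort(hits.begin(), hits.end());
        int keep = std::min((int)hits.size(), kmax);
        for (int h = 0; h < keep; ++h) {
          o_read.push_back(r + 1);
          o_ref.push_back(hits[h].refidx + 1);
          o_pos.push_back(hits[h].pos);
          o_strand.push_back(hits[h].strand);
          o_len.push_back(m);
          o_mm.push_back(hits[h].mm);
          o_step.push_back(step);
        }
        placed = true;
      }
    }
    status[r] = placed ? 0 : 1;
  }

  return List::create(
    _["read"] = wrap(o_read), _["ref"] = wrap(o_ref), _["pos"] = wrap(o_pos),
    _["strand"] = wrap(o_strand), _["len"] = wrap(o_len), _["mm"] = wrap(o_mm),
    _["step"] = wrap(o_step), _["status"] = status);
}
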
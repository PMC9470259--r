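// Virtual CPU for Avida-style digital organisms.
//
// A genome is a circular sequence of instructions over a 26-letter alphabet
// (ids 0..25 = letters a..z). One instruction effect is applied per cycle;
// nop modifiers following an instruction are consumed (they select the
// register/head operand and cost no cycle of their own). All words are
// unsigned 32-bit; comparisons are two's-complement signed; arithmetic wraps.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>

using namespace Rcpp;

enum InstId {
  NOPA = 0, NOPB, NOPC, IFNEQU, IFLESS, IFLABEL, MOVHEAD, JMPHEAD, GETHEAD,
  SETFLOW, SHIFTR, SHIFTL, INC, DEC, PUSH, POP, SWAPSTK, SWAP, ADD, SUB,
  NAND, HCOPY, HALLOC, HDIVIDE, IO, HSEARCH
};

// ---------------------------------------------------------------------------
// Counter-based environment stream (splitmix64 mixing): word n of environment
// (master_seed, env_id) is addressable without generating predecessors and is
// identical across platforms.

static inline uint64_t sm64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t env_key(uint64_t master_seed, uint64_t env_id) {
  return sm64(sm64(master_seed) ^ sm64(env_id ^ 0x6A09E667F3BCC909ULL));
}

static inline uint32_t env_word(uint64_t key, uint64_t n) {
  return (uint32_t)(sm64(key + n * 0x9E3779B97F4A7C15ULL) >> 32);
}

// [[Rcpp::export]]
NumericVector cpp_env_words(double master_seed, double env_id, int n, double from) {
  uint64_t key = env_key((uint64_t)master_seed, (uint64_t)env_id);
  NumericVector out(n);
  for (int i = 0; i < n; i++)
    out[i] = (double)env_word(key, (uint64_t)from + (uint64_t)i);
  return out;
}

// ---------------------------------------------------------------------------
// Logic-operation checking. Bit order of the phenotype code:
// NOT=0, NAND=1, AND=2, OR_N=3, OR=4, AND_N=5, NOR=6, XOR=7, EQU=8.

static inline int check_ops(uint32_t o, uint32_t a, uint32_t b) {
  int m = 0;
  if (o == (uint32_t)~a || o == (uint32_t)~b) m |= 1;          // NOT
  if (o == (uint32_t)~(a & b))                m |= 2;          // NAND
  if (o == (a & b))                           m |= 4;          // AND
  if (o == (a | (uint32_t)~b) || o == (b | (uint32_t)~a)) m |= 8;   // OR_N
  if (o == (a | b))                           m |= 16;         // OR
  if (o == (a & (uint32_t)~b) || o == (b & (uint32_t)~a)) m |= 32;  // AND_N
  if (o == (uint32_t)~(a | b))                m |= 64;         // NOR
  if (o == (a ^ b))                           m |= 128;        // XOR
  if (o == (uint32_t)~(a ^ b))                m |= 256;        // EQU
  return m;
}

// [[Rcpp::export]]
IntegerVector cpp_check_output(NumericVector output, NumericVector input1,
                               NumericVector input2) {
  int n = output.size();
  IntegerVector res(n);
  for (int i = 0; i < n; i++)
    res[i] = check_ops((uint32_t)output[i], (uint32_t)input1[i],
                       (uint32_t)input2[i]);
  return res;
}

// ---------------------------------------------------------------------------
// Gestation run

struct RunResult {
  bool divided, truncated;
  int cycles;
  std::vector<int> tpos;
  std::vector<uint8_t> tinst;
  std::vector<uint32_t> outs, oin1, oin2;
  std::vector<int> omask;
  std::vector<uint8_t> offspring;
  int opmask;
};

static inline int comp_reg(int r) { return (r + 1) % 3; }

static void run_cpu(const std::vector<uint8_t>& gen, uint64_t key,
                    int max_cycles, int min_off, double copy_frac,
                    int start, bool record_trace, RunResult& R) {
  const int L = (int)gen.size();
  std::vector<uint8_t> mem(gen);
  int memlen = L;
  bool allocated = false;

  uint32_t reg[3];
  reg[0] = 0;
  reg[1] = env_word(key, 0);          // BX pre-loaded from the environment
  reg[2] = 0;
  uint32_t in1 = env_word(key, 1), in2 = env_word(key, 2);
  uint64_t ctr = 3;                   // next stream word to consume

  std::vector<uint32_t> stk[2];
  int astk = 0;
  int ip = start % L, rh = start % L, wh = start % L, fh = start % L;
  std::vector<uint8_t> copied(L, 0);
  int ncopies = 0;
  std::vector<uint8_t> chist;         // most recently copied instructions

  R.divided = false; R.truncated = false; R.opmask = 0;
  R.tpos.clear(); R.tinst.clear();
  R.outs.clear(); R.oin1.clear(); R.oin2.clear(); R.omask.clear();
  R.offspring.clear();

  int cycles = 0;
  while (cycles < max_cycles) {
    const int pos = ip;
    const int inst = mem[pos];
    if (record_trace) { R.tpos.push_back(pos); R.tinst.push_back((uint8_t)inst); }
    cycles++;

    bool advance = true;
    int used = 0;        // nop modifiers consumed
    int extra_skip = 0;  // conditional skip of the following instruction

    auto nop_at = [&](int off) -> int {
      int v = mem[(ip + off) % memlen];
      return (v <= NOPC) ? v : -1;
    };
    auto mod_op = [&](int def) -> int {
      int v = nop_at(1);
      if (v >= 0) { used = 1; return v; }
      return def;
    };
    auto read_label = [&](std::vector<uint8_t>& lab) {
      int off = 1;
      while ((int)lab.size() < 10) {
        int v = nop_at(off);
        if (v < 0) break;
        lab.push_back((uint8_t)v);
        off++;
      }
      used = (int)lab.size();
    };

    switch (inst) {
    case NOPA: case NOPB: case NOPC:
      break;
    case IFNEQU: {
      int r = mod_op(1), c = comp_reg(r);
      if (!((int32_t)reg[r] != (int32_t)reg[c])) extra_skip = 1;
    } break;
    case IFLESS: {
      int r = mod_op(1), c = comp_reg(r);
      if (!((int32_t)reg[r] < (int32_t)reg[c])) extra_skip = 1;
    } break;
    case IFLABEL: {
      std::vector<uint8_t> lab;
      read_label(lab);
      bool match = false;
      if (!lab.empty() && chist.size() >= lab.size()) {
        match = true;
        for (size_t i = 0; i < lab.size(); i++) {
          uint8_t want = (uint8_t)((lab[i] + 1) % 3);
          if (chist[chist.size() - lab.size() + i] != want) { match = false; break; }
        }
      }
      if (!match) extra_skip = 1;
    } break;
    case MOVHEAD: {
      int h = mod_op(0);
      if (h == 0) { ip = fh; advance = false; }  // resume exactly at flow-head
      else if (h == 1) rh = fh;
      else wh = fh;
    } break;
    case JMPHEAD: {
      int h = mod_op(0);
      int jump = (int)(reg[2] % (uint32_t)memlen);
      if (h == 0) { ip = (ip + jump + 1) % memlen; advance = false; }
      else if (h == 1) rh = (rh + jump) % memlen;
      else wh = (wh + jump) % memlen;
    } break;
    case GETHEAD: {
      int h = mod_op(0);
      reg[2] = (uint32_t)(h == 0 ? ip : (h == 1 ? rh : wh));
    } break;
    case SETFLOW: {
      int r = mod_op(2);
      fh = (int)(reg[r] % (uint32_t)memlen);
    } break;
    case SHIFTR: { int r = mod_op(1); reg[r] >>= 1; } break;
    case SHIFTL: { int r = mod_op(1); reg[r] <<= 1; } break;
    case INC:    { int r = mod_op(1); reg[r] += 1; } break;
    case DEC:    { int r = mod_op(1); reg[r] -= 1; } break;
    case PUSH:   { int r = mod_op(1); stk[astk].push_back(reg[r]); } break;
    case POP: {
      int r = mod_op(1);
      if (stk[astk].empty()) reg[r] = 0;
      else { reg[r] = stk[astk].back(); stk[astk].pop_back(); }
    } break;
    case SWAPSTK: astk = 1 - astk; break;
    case SWAP: {
      int r = mod_op(1), c = comp_reg(r);
      uint32_t t = reg[r]; reg[r] = reg[c]; reg[c] = t;
    } break;
    case ADD:  { int r = mod_op(1); reg[r] = reg[1] + reg[2]; } break;
    case SUB:  { int r = mod_op(1); reg[r] = reg[1] - reg[2]; } break;
    case NAND: { int r = mod_op(1); reg[r] = ~(reg[1] & reg[2]); } break;
    case HCOPY: {
      mem[wh] = mem[rh];
      copied[wh] = 1;
      ncopies++;
      chist.push_back(mem[rh]);
      if (chist.size() > 10) chist.erase(chist.begin());
      rh = (rh + 1) % memlen;
      wh = (wh + 1) % memlen;
    } break;
    case HALLOC: {
      if (!allocated) {
        allocated = true;
        mem.resize(memlen + L, (uint8_t)NOPA);
        copied.resize(memlen + L, 0);
        memlen += L;
      }
    } break;
    case HDIVIDE: {
      int offlen = (wh - rh + memlen) % memlen;
      if (ncopies > 0 && offlen >= min_off) {
        int nc = 0;
        for (int i = 0; i < offlen; i++) nc += copied[(rh + i) % memlen];
        if ((double)nc / offlen >= copy_frac) {
          R.offspring.resize(offlen);
          for (int i = 0; i < offlen; i++)
            R.offspring[i] = mem[(rh + i) % memlen];
          R.divided = true;
        }
      }
    } break;
    case IO: {
      int r = mod_op(1);
      uint32_t o = reg[r];
      int m = check_ops(o, in1, in2);
      if (record_trace) {
        R.outs.push_back(o); R.oin1.push_back(in1); R.oin2.push_back(in2);
        R.omask.push_back(m);
      }
      R.opmask |= m;
      uint32_t nw = env_word(key, ctr++);
      in2 = in1; in1 = nw; reg[r] = nw;
    } break;
    case HSEARCH: {
      std::vector<uint8_t> lab;
      read_label(lab);
      if (lab.empty()) {
        fh = (ip + 1) % memlen;
        reg[1] = 0; reg[2] = 0;
      } else {
        const int s = (int)lab.size();
        std::vector<uint8_t> want(s);
        for (int i = 0; i < s; i++) want[i] = (uint8_t)((lab[i] + 1) % 3);
        int found = -1;
        for (int d = 0; d < memlen; d++) {
          int q = (ip + 1 + s + d) % memlen;
          bool ok = true;
          for (int i = 0; i < s; i++)
            if (mem[(q + i) % memlen] != want[i]) { ok = false; break; }
          if (ok) { found = q; break; }
        }
        if (found >= 0) {
          fh = (found + s) % memlen;
          reg[1] = (uint32_t)((found - ip + memlen) % memlen);
          reg[2] = (uint32_t)s;
        } else {
          fh = (ip + 1 + s) % memlen;
          reg[1] = 0; reg[2] = 0;
        }
      }
    } break;
    }

    if (R.divided) break;
    if (advance) ip = (ip + 1 + used + extra_skip) % memlen;
  }
  R.cycles = cycles;
  R.truncated = !R.divided && cycles >= max_cycles;
}

// io_count needs the trace only for positions; count IO executions separately
static int count_io(const RunResult& R) {
  int n = 0;
  for (size_t i = 0; i < R.tinst.size(); i++) if (R.tinst[i] == IO) n++;
  return n;
}

// FNV-1a 64-bit over the (position, instruction) step sequence
static std::string trace_key(const RunResult& R) {
  uint64_t h = 0xcbf29ce484222325ULL;
  for (size_t i = 0; i < R.tpos.size(); i++) {
    uint32_t p = (uint32_t)R.tpos[i];
    uint8_t bytes[5] = {
      (uint8_t)(p & 0xff), (uint8_t)((p >> 8) & 0xff),
      (uint8_t)((p >> 16) & 0xff), (uint8_t)((p >> 24) & 0xff),
      R.tinst[i]
    };
    for (int b = 0; b < 5; b++) {
      h ^= bytes[b];
      h *= 0x100000001b3ULL;
    }
  }
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}

static std::vector<uint8_t> to_gen(const IntegerVector& g) {
  std::vector<uint8_t> v(g.size());
  for (int i = 0; i < g.size(); i++) v[i] = (uint8_t)g[i];
  return v;
}

// [[Rcpp::export]]
List cpp_run_gestation(IntegerVector genome, double master_seed, double env_id,
                       int max_cycles, int min_offspring_length,
                       double require_copied_fraction, int start,
                       bool record_trace) {
  std::vector<uint8_t> gen = to_gen(genome);
  uint64_t key = env_key((uint64_t)master_seed, (uint64_t)env_id);
  RunResult R;
  run_cpu(gen, key, max_cycles, min_offspring_length, require_copied_fraction,
          start, record_trace, R);
  NumericVector outs(R.outs.size()), o1(R.outs.size()), o2(R.outs.size());
  IntegerVector om(R.outs.size());
  for (size_t i = 0; i < R.outs.size(); i++) {
    outs[i] = (double)R.outs[i];
    o1[i] = (double)R.oin1[i];
    o2[i] = (double)R.oin2[i];
    om[i] = R.omask[i];
  }
  IntegerVector off(R.offspring.size());
  for (size_t i = 0; i < R.offspring.size(); i++) off[i] = R.offspring[i];
  return List::create(
    _["divided"] = R.divided,
    _["truncated"] = R.truncated,
    _["cycles"] = R.cycles,
    _["trace_pos"] = IntegerVector(R.tpos.begin(), R.tpos.end()),
    _["trace_inst"] = IntegerVector(R.tinst.begin(), R.tinst.end()),
    _["outputs"] = outs,
    _["out_in1"] = o1,
    _["out_in2"] = o2,
    _["out_mask"] = om,
    _["op_mask"] = R.opmask,
    _["offspring"] = off,
    _["transcriptome_key"] = record_trace ? trace_key(R) : std::string(""));
}

// Viability: divides AND (offspring identical to parent, or the offspring's
// own gestation in the same environment divides successfully).
static bool viable_in_env(const std::vector<uint8_t>& gen, uint64_t key,
                          int max_cycles, int min_off, double frac,
                          RunResult& parentR) {
  run_cpu(gen, key, max_cycles, min_off, frac, 0, true, parentR);
  if (!parentR.divided) return false;
  if (parentR.offspring == gen) return true;
  if (parentR.offspring.empty()) return false;
  RunResult childR;
  run_cpu(parentR.offspring, key, max_cycles, min_off, frac, 0, false, childR);
  return childR.divided;
}

// [[Rcpp::export]]
bool cpp_is_viable(IntegerVector genome, double master_seed, double env_id,
                   int max_cycles, int min_offspring_length,
                   double require_copied_fraction) {
  std::vector<uint8_t> gen = to_gen(genome);
  uint64_t key = env_key((uint64_t)master_seed, (uint64_t)env_id);
  RunResult R;
  return viable_in_env(gen, key, max_cycles, min_offspring_length,
                       require_copied_fraction, R);
}

// ---------------------------------------------------------------------------
// Tandem repeats: maximal leftmost-longest periodic runs of the position
// sequence, >= 2 full copies of a period-p block; at a given start the run
// with the largest full-period coverage wins, ties broken by smallest period;
// runs do not overlap (greedy left-to-right).

static void find_runs(const std::vector<int>& x, std::vector<int>& rs,
                      std::vector<int>& rp, std::vector<int>& rk) {
  const int n = (int)x.size();
  int s = 0;
  while (s < n) {
    int bestp = 0, bestk = 0, bestlen = 0;
    const int maxp = (n - s) / 2;
    for (int p = 1; p <= maxp; p++) {
      if (x[s] != x[s + p]) continue;
      int i = s;
      while (i + p < n && x[i] == x[i + p]) i++;
      const int t = i - s;          // matched offsets
      if (t < p) continue;          // fewer than 2 full copies
      const int k = (t + p) / p;    // full copies
      const int len = k * p;        // full-period coverage
      if (len > bestlen) { bestlen = len; bestp = p; bestk = k; }
    }
    if (bestlen > 0) {
      rs.push_back(s); rp.push_back(bestp); rk.push_back(bestk);
      s += bestlen;
    } else {
      s++;
    }
  }
}

// [[Rcpp::export]]
List cpp_tandem_repeats(IntegerVector pos) {
  std::vector<int> x(pos.begin(), pos.end());
  std::vector<int> rs, rp, rk;
  find_runs(x, rs, rp, rk);
  return List::create(
    _["start"] = IntegerVector(rs.begin(), rs.end()),
    _["period"] = IntegerVector(rp.begin(), rp.end()),
    _["count"] = IntegerVector(rk.begin(), rk.end()));
}

static int io_in_runs(const RunResult& R) {
  std::vector<int> rs, rp, rk;
  find_runs(R.tpos, rs, rp, rk);
  int n = 0;
  for (size_t j = 0; j < rs.size(); j++) {
    int from = rs[j], to = rs[j] + rp[j] * rk[j];
    for (int i = from; i < to; i++) if (R.tinst[i] == IO) n++;
  }
  return n;
}

// ---------------------------------------------------------------------------
// Per-genome profiling across an environment set

// [[Rcpp::export]]
List cpp_profile(IntegerVector genome, double master_seed,
                 IntegerVector env_ids, int max_cycles,
                 int min_offspring_length, double require_copied_fraction) {
  std::vector<uint8_t> gen = to_gen(genome);
  const int ne = env_ids.size();
  LogicalVector viable(ne), divided(ne), truncated(ne);
  IntegerVector phenotype(ne), tlen(ne), io_count(ne), io_rep(ne);
  CharacterVector tkey(ne);
  RunResult R;
  for (int e = 0; e < ne; e++) {
    uint64_t key = env_key((uint64_t)master_seed, (uint64_t)env_ids[e]);
    bool v = viable_in_env(gen, key, max_cycles, min_offspring_length,
                           require_copied_fraction, R);
    viable[e] = v;
    divided[e] = R.divided;
    truncated[e] = R.truncated;
    tlen[e] = R.cycles;
    io_count[e] = count_io(R);
    tkey[e] = trace_key(R);
    if (v) {
      phenotype[e] = R.opmask;
      io_rep[e] = io_in_runs(R);
    } else {
      phenotype[e] = NA_INTEGER;
      io_rep[e] = NA_INTEGER;
    }
  }
  return List::create(
    _["env_id"] = env_ids,
    _["viable"] = viable,
    _["divided"] = divided,
    _["truncated"] = truncated,
    _["phenotype"] = phenotype,
    _["transcriptome_key"] = tkey,
    _["transcriptome_length"] = tlen,
    _["io_count"] = io_count,
    _["io_in_repeats"] = io_rep);
}
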
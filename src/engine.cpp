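// Discrete-tick spatial engine for the transcription / mRNA-decay
// cross-talk multi-agent model.  One call simulates one complete run and
// returns the append-only event log; all readouts are derived from the log
// on the R side, so the C++ and pure-R engines share a single metrics path.
//
// Phase order inside a tick (fixed, documented):
//   movement -> initiation -> elongation updates -> factor actions
//   (Ccr4-Not first, then TFIIS) -> termination -> mRNA lifecycle.
// Ties (several eligible targets at equal distance) are broken by lowest
// agent id; proximity is a closed ball (distance <= radius).

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Event codes: keep in sync with event_codes() in R/engine.R.
enum Ev {
  EV_INITIATION = 1, EV_CLASS_AX = 2, EV_BACKTRACK = 3, EV_INACTIVATE = 4,
  EV_TFIIS_RESCUE = 5, EV_TFIIS_RESCUE_I = 6, EV_CCR4_REACTIVATE = 7,
  EV_CCR4_PREVENT = 8, EV_CCR4_RECRUIT = 9, EV_CCR4_ENHANCE = 10,
  EV_CCR4_RESCUE = 11, EV_SPONT_REACTIVATE = 12, EV_DROPOFF = 13,
  EV_TERMINATION = 14, EV_MRNA_BIRTH = 15, EV_EXPORT = 16,
  EV_DECAY_ENGAGE = 17, EV_DEGRADATION_COMPLETE = 18, EV_BASAL_DECAY = 19,
  EV_MRNA_DEATH = 20, EV_IMPRINT_BIND = 21, EV_IMPRINT_TRANSFER = 22
};

// Polymerase phases / elongation classes.
enum PolPhase { P_FREE = 0, P_GENE = 1 };
enum PolClass { C_A0 = 0, C_AX = 1, C_AC = 2, C_I = 3, C_IB = 4 };
// In model 1, C_A0 doubles as "elongating" and C_IB as "backtracked".

struct Rng {
  std::mt19937_64 g;
  explicit Rng(uint64_t seed) : g(seed) {}
  double u() { // uniform in [0, 1)
    return std::uniform_real_distribution<double>(0.0, 1.0)(g);
  }
};

struct Vec3 { double x = 0, y = 0, z = 0; };

static inline double norm3(const Vec3 &p) {
  return std::sqrt(p.x * p.x + p.y * p.y + p.z * p.z);
}
static inline double dist3(const Vec3 &a, const Vec3 &b) {
  double dx = a.x - b.x, dy = a.y - b.y, dz = a.z - b.z;
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// isotropic step of length s
static inline Vec3 rand_step(Rng &rng, double s) {
  double zc = 2.0 * rng.u() - 1.0;
  double phi = 2.0 * M_PI * rng.u();
  double rxy = std::sqrt(std::max(0.0, 1.0 - zc * zc));
  Vec3 d;
  d.x = s * rxy * std::cos(phi);
  d.y = s * rxy * std::sin(phi);
  d.z = s * zc;
  return d;
}

// uniform point in a ball of radius R (rejection from the bounding cube)
static inline Vec3 rand_in_ball(Rng &rng, double R) {
  Vec3 p;
  do {
    p.x = (2.0 * rng.u() - 1.0) * R;
    p.y = (2.0 * rng.u() - 1.0) * R;
    p.z = (2.0 * rng.u() - 1.0) * R;
  } while (norm3(p) > R);
  return p;
}

// reflect at an outer spherical boundary of radius R
static inline void reflect_outer(Vec3 &p, double R) {
  double r = norm3(p);
  if (r > R) {
    double rr = 2.0 * R - r;
    if (rr < 0) rr = R; // pathological overshoot: clamp to the boundary
    double f = (r > 0) ? rr / r : 0.0;
    p.x *= f; p.y *= f; p.z *= f;
  }
}

// reflect at an inner spherical boundary (keep r >= R), then clamp outer
static inline void reflect_inner(Vec3 &p, double Rin, double Rout) {
  double r = norm3(p);
  if (r < Rin) {
    double rr = 2.0 * Rin - r;
    if (rr > Rout) rr = Rout;
    double f = (r > 1e-12) ? rr / r : 0.0;
    if (f == 0.0) { p.x = Rin; p.y = 0; p.z = 0; }
    else { p.x *= f; p.y *= f; p.z *= f; }
  }
}

struct Pol {
  Vec3 pos;
  int phase = P_FREE;
  int cls = C_A0;
  int gene_pos = 0;     // 1..L while on gene
  bool immune = false;  // model 1, ccr4_mode = prevent
  int rider = -1;       // ccr4 index riding this polymerase (imprinting)
};

enum FacType { F_TFIIS = 0, F_CCR4 = 1, F_XRN1 = 2 };
enum FacBusy { FB_FREE = 0, FB_RIDING_POL = 1, FB_RIDING_MRNA = 2,
               FB_DEGRADING = 3 };

struct Fac {
  int type;
  Vec3 pos;
  int busy = FB_FREE;
};

struct Mrna {
  Vec3 pos;
  int compartment = 0;  // 0 nucleus, 1 cytoplasm
  int engaged_by = -1;  // factor index degrading this mRNA
  int progress = 0;
  int imprint = -1;     // ccr4 factor index riding this mRNA
  bool alive = true;
};

struct Log {
  std::vector<int> tick, code, a1, a2;
  void add(int t, int c, int x1, int x2) {
    tick.push_back(t); code.push_back(c); a1.push_back(x1); a2.push_back(x2);
  }
};

// [[Rcpp::export]]
List engine_run_cpp(List cfg) {
  // --- unpack configuration -------------------------------------------
  const int nP = as<int>(cfg["n_polymerase"]);
  const int nT = as<int>(cfg["n_tfiis"]);
  const int nC = as<int>(cfg["n_ccr4"]);
  const int nX = as<int>(cfg["n_xrn1"]);
  const int L = as<int>(cfg["gene_length"]);
  const double Rn = as<double>(cfg["nucleus_radius"]);
  const double Rc = as<double>(cfg["cytoplasm_radius"]);
  const double r_tfiis = as<double>(cfg["radius_tfiis"]);
  const double r_ccr4 = as<double>(cfg["radius_ccr4"]);
  const double r_prom = as<double>(cfg["radius_promoter_contact"]);
  const double r_xprom = as<double>(cfg["radius_xrn1_promoter"]);
  const double r_decay = as<double>(cfg["radius_decay"]);
  const double s_pol = as<double>(cfg["step_polymerase"]);
  const double s_tfiis = as<double>(cfg["step_tfiis"]);
  const double s_ccr4 = as<double>(cfg["step_ccr4"]);
  const double s_xrn1 = as<double>(cfg["step_xrn1"]);
  const double s_mrna = as<double>(cfg["step_mrna"]);
  const double p_init = as<double>(cfg["p_init"]);
  const double xrn1_boost = as<double>(cfg["xrn1_boost"]);
  const double p_bt = as<double>(cfg["p_backtrack"]);
  const double p_inact = as<double>(cfg["p_inactivate"]);
  const double ac_scale = as<double>(cfg["ac_inactivate_scale"]);
  const double p_spont = as<double>(cfg["p_spontaneous_reactivate"]);
  const double p_drop = as<double>(cfg["p_dropoff"]);
  const int adv = as<int>(cfg["step_advance"]);
  const double ax_mult = as<double>(cfg["ax_speed_mult"]);
  const double ac_mult = as<double>(cfg["ac_speed_mult"]);
  const double p_basal = as<double>(cfg["mrna_basal_decay"]);
  const int deg_ticks = as<int>(cfg["degradation_ticks"]);
  const std::string model = as<std::string>(cfg["model"]);
  const std::string mode = as<std::string>(cfg["ccr4_mode"]);
  const bool feedback = as<bool>(cfg["xrn1_feedback"]);
  const bool imprinting = as<bool>(cfg["imprinting"]);
  const bool m2_boost = as<bool>(cfg["model2_rate_boost"]);
  const int burn = as<int>(cfg["burn_in_ticks"]);
  const int rec = as<int>(cfg["record_ticks"]);
  const uint64_t seed = static_cast<uint64_t>(as<double>(cfg["seed"]));

  const bool model2 = (model == "model2");
  const int n_ticks = burn + rec;
  const int adv_ax = std::max(1, (int)std::lround(adv * ax_mult));
  const int adv_ac = std::max(1, (int)std::lround(adv * ac_mult));

  Rng rng(seed ^ 0x9e3779b97f4a7c15ULL);

  // --- initial world ---------------------------------------------------
  std::vector<Pol> pol(nP);
  for (auto &p : pol) p.pos = rand_in_ball(rng, Rn);
  std::vector<Fac> fac; // global factor indexing: TFIIS, then Ccr4, then Xrn1
  for (int i = 0; i < nT; ++i) fac.push_back({F_TFIIS, rand_in_ball(rng, Rn)});
  for (int i = 0; i < nC; ++i) fac.push_back({F_CCR4, rand_in_ball(rng, Rc)});
  for (int i = 0; i < nX; ++i) fac.push_back({F_XRN1, rand_in_ball(rng, Rc)});
  const int nF = (int)fac.size();
  std::vector<Mrna> mrna;        // grows over the run; index = id - 1
  std::vector<int> occ(L + 1, -1); // gene position -> pol index (1-based pos)

  Log log;
  const Vec3 origin; // gene site = promoter = centre of the nucleus

  // factor agent ids reported in the log are offset past the polymerases
  auto fid = [&](int fi) { return nP + fi + 1; };

  for (int t = 1; t <= n_ticks; ++t) {
    // ---- phase 1: movement -------------------------------------------
    for (int i = 0; i < nP; ++i) {
      if (pol[i].phase != P_FREE) continue;
      Vec3 d = rand_step(rng, s_pol);
      pol[i].pos.x += d.x; pol[i].pos.y += d.y; pol[i].pos.z += d.z;
      reflect_outer(pol[i].pos, Rn); // RNAPII confined to the nucleus
    }
    for (int i = 0; i < nF; ++i) {
      if (fac[i].busy != FB_FREE) continue;
      double s = fac[i].type == F_TFIIS ? s_tfiis
               : fac[i].type == F_CCR4 ? s_ccr4 : s_xrn1;
      Vec3 d = rand_step(rng, s);
      fac[i].pos.x += d.x; fac[i].pos.y += d.y; fac[i].pos.z += d.z;
      if (fac[i].type == F_TFIIS) reflect_outer(fac[i].pos, Rn);
      else reflect_outer(fac[i].pos, Rc); // Xrn1/Ccr4 roam both compartments
    }
    for (size_t m = 0; m < mrna.size(); ++m) {
      if (!mrna[m].alive || mrna[m].engaged_by >= 0) continue;
      Vec3 d = rand_step(rng, s_mrna);
      mrna[m].pos.x += d.x; mrna[m].pos.y += d.y; mrna[m].pos.z += d.z;
      if (mrna[m].compartment == 0) {
        if (norm3(mrna[m].pos) > Rn) { // crossing the nuclear envelope
          mrna[m].compartment = 1;
          reflect_outer(mrna[m].pos, Rc);
          log.add(t, EV_EXPORT, (int)m + 1, 0);
        }
      } else {
        reflect_inner(mrna[m].pos, Rn, Rc);
        reflect_outer(mrna[m].pos, Rc);
      }
      if (mrna[m].imprint >= 0) fac[mrna[m].imprint].pos = mrna[m].pos;
    }

    // ---- phase 2: initiation -----------------------------------------
    if (occ[1] < 0) {
      int cand = -1; double best = 0;
      for (int i = 0; i < nP; ++i) {
        if (pol[i].phase != P_FREE) continue;
        double dd = dist3(pol[i].pos, origin);
        if (dd <= r_prom && (cand < 0 || dd < best)) { cand = i; best = dd; }
      }
      if (cand >= 0) {
        int n_xrn1_near = 0;
        for (int i = 0; i < nF; ++i)
          if (fac[i].type == F_XRN1 && fac[i].busy == FB_FREE &&
              norm3(fac[i].pos) <= Rn && dist3(fac[i].pos, origin) <= r_xprom)
            ++n_xrn1_near;
        double p = p_init;
        bool rate_boost = feedback && (!model2 || m2_boost);
        if (rate_boost) p = std::min(1.0, p_init * (1.0 + xrn1_boost * n_xrn1_near));
        if (rng.u() < p) {
          Pol &pp = pol[cand];
          pp.phase = P_GENE; pp.gene_pos = 1; pp.pos = origin;
          pp.immune = false; pp.rider = -1;
          pp.cls = C_A0;
          occ[1] = cand;
          log.add(t, EV_INITIATION, cand + 1, 0);
          if (model2 && feedback && n_xrn1_near >= 1) {
            pp.cls = C_AX;
            log.add(t, EV_CLASS_AX, cand + 1, 0);
          }
        }
      }
    }

    // ---- phase 3: elongation updates ---------------------------------
    // Process from the terminator backwards so a pol never collides with
    // one ahead of it that has not moved yet this tick.
    for (int posn = L; posn >= 1; --posn) {
      int i = occ[posn];
      if (i < 0) continue;
      Pol &pp = pol[i];
      auto advance = [&](int npos_step) {
        int target = std::min(L, pp.gene_pos + npos_step);
        int np = pp.gene_pos;
        for (int q = pp.gene_pos + 1; q <= target; ++q) {
          if (occ[q] >= 0) break;
          np = q;
        }
        if (np != pp.gene_pos) {
          occ[pp.gene_pos] = -1; occ[np] = i; pp.gene_pos = np;
        }
      };
      if (!model2) {
        if (pp.cls == C_A0) { // elongating
          if (!pp.immune && rng.u() < p_bt) {
            pp.cls = C_IB;
            log.add(t, EV_BACKTRACK, i + 1, 0);
          } else advance(adv);
        } else { // backtracked
          if (rng.u() < p_spont) {
            pp.cls = C_A0;
            log.add(t, EV_SPONT_REACTIVATE, i + 1, 0);
          }
        }
      } else {
        switch (pp.cls) {
        case C_AX: advance(adv_ax); break;
        case C_AC:
          if (rng.u() < p_inact * ac_scale) {
            pp.cls = C_I; log.add(t, EV_INACTIVATE, i + 1, 0);
          } else advance(adv_ac);
          break;
        case C_A0:
          if (rng.u() < p_inact) {
            pp.cls = C_I; log.add(t, EV_INACTIVATE, i + 1, 0);
          } else advance(adv);
          break;
        case C_I: // not rescued during the previous factor phase
          pp.cls = C_IB; log.add(t, EV_BACKTRACK, i + 1, 0);
          break;
        case C_IB:
          if (rng.u() < p_spont) {
            pp.cls = C_A0; log.add(t, EV_SPONT_REACTIVATE, i + 1, 0);
          } else if (rng.u() < p_drop) {
            occ[pp.gene_pos] = -1;
            pp.phase = P_FREE; pp.gene_pos = 0; pp.cls = C_A0;
            pp.pos = origin;
            if (pp.rider >= 0) { fac[pp.rider].busy = FB_FREE; pp.rider = -1; }
            log.add(t, EV_DROPOFF, i + 1, 0);
          }
          break;
        }
      }
    }

    // ---- phase 4: factor actions (Ccr4-Not first, then TFIIS) --------
    auto bind_rider = [&](int pi, int ci) {
      if (imprinting && pol[pi].rider < 0) {
        pol[pi].rider = ci; fac[ci].busy = FB_RIDING_POL;
        fac[ci].pos = origin;
        log.add(t, EV_IMPRINT_BIND, pi + 1, fid(ci));
      }
    };
    {
      for (int ci = 0; ci < nF; ++ci) {
        if (fac[ci].type != F_CCR4 || fac[ci].busy != FB_FREE) continue;
        if (norm3(fac[ci].pos) > Rn) continue;              // must be nuclear
        if (dist3(fac[ci].pos, origin) > r_ccr4) continue;  // within reach
        // all on-gene polymerases sit at the gene site: distance ties are
        // broken by lowest agent id (= ascending scan order)
        int target = -1;
        for (int i = 0; i < nP && target < 0; ++i) {
          if (pol[i].phase != P_GENE) continue;
          if (!model2) {
            if (mode == "prevent" && pol[i].cls == C_A0 && !pol[i].immune)
              target = i;
            else if ((mode == "reactivate" || mode == "recruit_tfiis") &&
                     pol[i].cls == C_IB)
              target = i;
          } else {
            if (pol[i].cls == C_A0 || pol[i].cls == C_I) target = i;
          }
        }
        if (target < 0) {
          // imprinting is a standing property of Ccr4-Not, independent of
          // the elongation-feedback mode: on contact it can bind any
          // on-gene polymerase without a rider and ride to termination
          if (imprinting) {
            for (int i = 0; i < nP; ++i) {
              if (pol[i].phase == P_GENE && pol[i].rider < 0) {
                bind_rider(i, ci);
                break;
              }
            }
          }
          continue;
        }
        if (!model2) {
          if (mode == "prevent") {
            pol[target].immune = true;
            log.add(t, EV_CCR4_PREVENT, target + 1, fid(ci));
            bind_rider(target, ci);
          } else if (mode == "reactivate") {
            pol[target].cls = C_A0;
            log.add(t, EV_CCR4_REACTIVATE, target + 1, fid(ci));
            bind_rider(target, ci);
          } else { // recruit_tfiis: needs an existing free TFIIS
            int ti = -1;
            for (int j = 0; j < nF; ++j)
              if (fac[j].type == F_TFIIS && fac[j].busy == FB_FREE) { ti = j; break; }
            if (ti >= 0) {
              fac[ti].pos = origin; // recruited to the gene
              pol[target].cls = C_A0;
              log.add(t, EV_CCR4_RECRUIT, target + 1, fid(ci));
              log.add(t, EV_TFIIS_RESCUE, target + 1, fid(ti));
              bind_rider(target, ci);
            }
          }
        } else {
          bool was_inactive = (pol[target].cls == C_I);
          pol[target].cls = C_AC;
          log.add(t, was_inactive ? EV_CCR4_RESCUE : EV_CCR4_ENHANCE,
                  target + 1, fid(ci));
          bind_rider(target, ci);
        }
      }
    }
    for (int ti = 0; ti < nF; ++ti) {
      if (fac[ti].type != F_TFIIS || fac[ti].busy != FB_FREE) continue;
      if (dist3(fac[ti].pos, origin) > r_tfiis) continue;
      int target = -1; bool from_i = false;
      for (int i = 0; i < nP && target < 0; ++i) {
        if (pol[i].phase != P_GENE) continue;
        if (pol[i].cls == C_IB) { target = i; from_i = false; }
        else if (model2 && pol[i].cls == C_I) { target = i; from_i = true; }
      }
      if (target < 0) continue;
      pol[target].cls = C_A0; // rescue restarts at the current position
      log.add(t, from_i ? EV_TFIIS_RESCUE_I : EV_TFIIS_RESCUE,
              target + 1, fid(ti));
    }

    // ---- phase 5: termination ----------------------------------------
    if (occ[L] >= 0) {
      int i = occ[L];
      Pol &pp = pol[i];
      // only an actively elongating polymerase terminates
      bool active = (!model2 && pp.cls == C_A0) ||
                    (model2 && (pp.cls == C_A0 || pp.cls == C_AX || pp.cls == C_AC));
      if (active) {
        occ[L] = -1;
        pp.phase = P_FREE; pp.gene_pos = 0; pp.pos = origin;
        log.add(t, EV_TERMINATION, i + 1, 0);
        Mrna m;
        m.pos = origin; m.compartment = 0;
        int mid = (int)mrna.size() + 1;
        if (pp.rider >= 0) {
          m.imprint = pp.rider;
          fac[pp.rider].busy = FB_RIDING_MRNA;
          fac[pp.rider].pos = origin;
          log.add(t, EV_IMPRINT_TRANSFER, mid, fid(pp.rider));
          pp.rider = -1;
        }
        pp.cls = C_A0; pp.immune = false;
        mrna.push_back(m);
        log.add(t, EV_MRNA_BIRTH, mid, i + 1);
      }
    }

    // ---- phase 6: mRNA lifecycle -------------------------------------
    for (size_t m = 0; m < mrna.size(); ++m) {
      Mrna &mm = mrna[m];
      if (!mm.alive) continue;
      int mid = (int)m + 1;
      if (mm.compartment == 1 && mm.engaged_by < 0) {
        if (mm.imprint >= 0) { // imprinted mRNA: immediate engagement
          mm.engaged_by = mm.imprint;
          fac[mm.imprint].busy = FB_DEGRADING;
          log.add(t, EV_DECAY_ENGAGE, mid, fid(mm.imprint));
        } else {
          int best = -1; double bd = 0;
          for (int j = 0; j < nF; ++j) {
            if (fac[j].busy != FB_FREE) continue;
            if (fac[j].type != F_CCR4 && fac[j].type != F_XRN1) continue;
            if (norm3(fac[j].pos) <= Rn) continue; // must be cytoplasmic
            double dd = dist3(fac[j].pos, mm.pos);
            if (dd <= r_decay && (best < 0 || dd < bd)) { best = j; bd = dd; }
          }
          if (best >= 0) {
            mm.engaged_by = best;
            fac[best].busy = FB_DEGRADING;
            fac[best].pos = mm.pos;
            log.add(t, EV_DECAY_ENGAGE, mid, fid(best));
          }
        }
      }
      if (mm.engaged_by >= 0) {
        if (++mm.progress >= deg_ticks) {
          log.add(t, EV_DEGRADATION_COMPLETE, mid, fid(mm.engaged_by));
          fac[mm.engaged_by].busy = FB_FREE; // freed factor may roam back
          mm.engaged_by = -1; mm.imprint = -1; mm.alive = false;
          log.add(t, EV_MRNA_DEATH, mid, 0);
        }
      } else if (p_basal > 0 && rng.u() < p_basal) {
        if (mm.imprint >= 0) fac[mm.imprint].busy = FB_FREE;
        mm.imprint = -1; mm.alive = false;
        log.add(t, EV_BASAL_DECAY, mid, 0);
        log.add(t, EV_MRNA_DEATH, mid, 0);
      }
    }
  }

  int n = (int)log.tick.size();
  IntegerMatrix ev(n, 4);
  for (int i = 0; i < n; ++i) {
    ev(i, 0) = log.tick[i]; ev(i, 1) = log.code[i];
    ev(i, 2) = log.a1[i];   ev(i, 3) = log.a2[i];
  }
  colnames(ev) = CharacterVector::create("tick", "code", "a1", "a2");
  return List::create(_["events"] = ev, _["n_ticks"] = n_ticks,
                      _["n_mrna_total"] = (int)mrna.size());
}
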
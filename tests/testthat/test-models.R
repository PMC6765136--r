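# Rule-set behaviour: state-machine closure, knockout nullity, variant
# separation, class-speed ordering.  Runs use the C++ engine (the R engine
# is equivalence-tested separately) with 10^4-tick logs.

long_run <- function(..., seed = 101L) {
  run_sim(sim_config(base = unclass(default_config()), burn_in_ticks = 0L,
                     record_ticks = 10000L, seed = seed, ...),
          metrics = FALSE)
}

test_that("knockout nullity: a zeroed pool produces zero events of that factor", {
  grid <- expand.grid(model = c("model1", "model2"),
                      mode = c("prevent", "reactivate", "recruit_tfiis", "none"),
                      stringsAsFactors = FALSE)
  grid <- grid[grid$model == "model1" | grid$mode == "reactivate", ]
  for (k in seq_len(nrow(grid))) {
    r_dst1 <- long_run(model = grid$model[k], ccr4_mode = grid$mode[k],
                       n_tfiis = 0L)
    expect_identical(count_events(r_dst1, "tfiis_rescue") +
                       count_events(r_dst1, "tfiis_rescue_i") +
                       count_events(r_dst1, "ccr4_recruit"), 0L)
    r_ccr4 <- long_run(model = grid$model[k], ccr4_mode = grid$mode[k],
                       n_ccr4 = 0L)
    expect_identical(sum(r_ccr4$events$event %in%
      c("ccr4_reactivate", "ccr4_prevent", "ccr4_recruit", "ccr4_enhance",
        "ccr4_rescue", "imprint_bind", "imprint_transfer")), 0L)
    r_xrn1 <- long_run(model = grid$model[k], ccr4_mode = grid$mode[k],
                       n_xrn1 = 0L)
    expect_identical(count_events(r_xrn1, "class_ax"), 0L)
  }
})

test_that("state-transition closure: logged per-polymerase event sequences
           only use legal edges", {
  legal_next <- list(
    model1 = list(
      initiation = c("backtrack", "termination", "initiation"),
      backtrack = c("tfiis_rescue", "ccr4_reactivate", "ccr4_recruit",
                    "spont_reactivate", "ccr4_prevent"),
      tfiis_rescue = c("backtrack", "termination", "initiation"),
      ccr4_reactivate = c("backtrack", "termination", "initiation"),
      ccr4_recruit = "tfiis_rescue",
      spont_reactivate = c("backtrack", "termination", "initiation"),
      ccr4_prevent = c("termination", "initiation", "backtrack"),
      imprint_bind = "*", termination = "initiation"
    ),
    model2 = list(
      initiation = c("class_ax", "inactivate", "ccr4_enhance", "termination",
                     "initiation"),
      class_ax = c("termination", "initiation"),
      inactivate = c("tfiis_rescue_i", "ccr4_rescue", "backtrack"),
      backtrack = c("tfiis_rescue", "spont_reactivate", "dropoff"),
      tfiis_rescue = c("inactivate", "ccr4_enhance", "termination",
                       "initiation"),
      tfiis_rescue_i = c("inactivate", "ccr4_enhance", "termination",
                         "initiation"),
      ccr4_rescue = c("inactivate", "termination", "initiation"),
      ccr4_enhance = c("inactivate", "termination", "initiation"),
      spont_reactivate = c("inactivate", "ccr4_enhance", "termination",
                           "initiation"),
      dropoff = "initiation", imprint_bind = "*", termination = "initiation"
    )
  )
  for (model in c("model1", "model2")) {
    run <- long_run(model = model, seed = 55L)
    ev <- run$events
    pol_ev <- ev[ev$event %in% names(legal_next[[model]]) &
                   ev$event != "imprint_bind", ]
    for (pid in unique(pol_ev$a1)) {
      seq_ev <- pol_ev$event[pol_ev$a1 == pid]
      if (length(seq_ev) < 2) next
      for (i in seq_len(length(seq_ev) - 1)) {
        allowed <- legal_next[[model]][[seq_ev[i]]]
        expect_true(identical(allowed, "*") || seq_ev[i + 1] %in% allowed,
                    label = sprintf("%s: %s -> %s legal", model, seq_ev[i],
                                    seq_ev[i + 1]))
      }
    }
  }
})

test_that("A_x polymerases never backtrack or inactivate (model 2)", {
  run <- long_run(model = "model2", seed = 77L)
  ev <- run$events
  # within each transcription cycle, an A_x classification excludes any
  # inactivate/backtrack event until termination
  for (pid in unique(ev$a1[ev$event == "class_ax"])) {
    pe <- ev[ev$a1 == pid & ev$event %in%
               c("initiation", "class_ax", "inactivate", "backtrack",
                 "termination"), ]
    ax_on <- FALSE
    for (i in seq_len(nrow(pe))) {
      e <- pe$event[i]
      if (e == "class_ax") ax_on <- TRUE
      if (e %in% c("termination", "initiation") && e != "class_ax")
        ax_on <- if (e == "initiation") FALSE else FALSE
      if (ax_on) expect_false(e %in% c("inactivate", "backtrack"))
    }
  }
  expect_gt(count_events(run, "class_ax"), 0L)
})

test_that("variant separation: ccr4_mode none matches the ccr4 null;
           prevent suppresses backtracking of touched polymerases", {
  r_none <- long_run(model = "model1", ccr4_mode = "none", seed = 9L)
  r_ko <- long_run(model = "model1", ccr4_mode = "reactivate", n_ccr4 = 0L,
                   seed = 9L)
  # identical seeds give different trajectories (extra roaming agents) but
  # Ccr4 contributes zero transcription events in both
  for (r in list(r_none, r_ko))
    expect_identical(sum(r$events$event %in%
      c("ccr4_reactivate", "ccr4_prevent", "ccr4_recruit")), 0L)
  bt_rate <- function(r) count_events(r, "backtrack") /
    max(1L, count_events(r, "initiation"))
  expect_equal(bt_rate(r_none), bt_rate(r_ko), tolerance = 0.25)
  # prevent: an immune polymerase finishes its cycle without backtracking
  r_prev <- long_run(model = "model1", ccr4_mode = "prevent", seed = 12L)
  ev <- r_prev$events
  for (i in which(ev$event == "ccr4_prevent")) {
    pid <- ev$a1[i]
    # log rows preserve intra-tick phase order: termination in the same
    # tick as the prevent action already ends the protected cycle
    later <- ev[seq_len(nrow(ev)) > i & ev$a1 == pid, ]
    term <- which(later$event == "termination")[1]
    if (is.na(term)) next
    expect_identical(sum(later$event[seq_len(term)] == "backtrack"), 0L)
  }
})

test_that("model-2 class speed ordering: Ax faster than Ac/A0 cycles", {
  run <- long_run(model = "model2", seed = 31L)
  ev <- run$events
  term <- ev[ev$event == "termination", ]
  init <- ev[ev$event == "initiation", ]
  ax <- ev[ev$event == "class_ax", ]
  cyc <- data.frame(pid = term$a1, t1 = term$tick)
  cyc$t0 <- vapply(seq_len(nrow(cyc)), function(i)
    max(init$tick[init$a1 == cyc$pid[i] & init$tick <= cyc$t1[i]]), 1)
  cyc$is_ax <- vapply(seq_len(nrow(cyc)), function(i)
    any(ax$a1 == cyc$pid[i] & ax$tick >= cyc$t0[i] & ax$tick <= cyc$t1[i]),
    logical(1))
  cyc$len <- cyc$t1 - cyc$t0 + 1
  expect_gt(sum(cyc$is_ax), 20)
  expect_gt(sum(!cyc$is_ax), 20)
  expect_lt(mean(cyc$len[cyc$is_ax]), mean(cyc$len[!cyc$is_ax]))
})

test_that("imprinting: riding Ccr4 transfers to the mRNA and engages at export", {
  run <- long_run(model = "model1", ccr4_mode = "reactivate", seed = 21L)
  ev <- run$events
  tr <- ev[ev$event == "imprint_transfer", ]
  expect_gt(nrow(tr), 0L)
  for (i in seq_len(nrow(tr))) {
    mid <- tr$a1[i]
    exp_t <- ev$tick[ev$event == "export" & ev$a1 == mid]
    eng <- ev[ev$event == "decay_engage" & ev$a1 == mid, ]
    if (!length(exp_t) || !nrow(eng)) next
    # engagement happens the same tick as export (zero search time) and by
    # the riding Ccr4
    expect_identical(eng$tick[1], exp_t[1])
    expect_identical(eng$a2[1], tr$a2[i])
  }
  # imprinting off -> no binding anywhere
  r_off <- long_run(model = "model1", ccr4_mode = "reactivate",
                    imprinting = FALSE, seed = 21L)
  expect_identical(sum(r_off$events$event %in%
    c("imprint_bind", "imprint_transfer")), 0L)
})

test_that("recruit mode requires an existing TFIIS and rescues via TFIIS", {
  r <- long_run(model = "model1", ccr4_mode = "recruit_tfiis", seed = 41L)
  n_recruit <- count_events(r, "ccr4_recruit")
  expect_gt(n_recruit, 0L)
  # every recruit is immediately followed by a TFIIS rescue of the same pol
  ev <- r$events
  idx <- which(ev$event == "ccr4_recruit")
  expect_true(all(ev$event[idx + 1] == "tfiis_rescue" &
                    ev$a1[idx + 1] == ev$a1[idx]))
  r0 <- long_run(model = "model1", ccr4_mode = "recruit_tfiis", n_tfiis = 0L,
                 seed = 41L)
  expect_identical(count_events(r0, "ccr4_recruit"), 0L)
  expect_identical(count_events(r0, "tfiis_rescue"), 0L)
})

test_that("p_spontaneous_reactivate = 1 resumes a backtracked polymerase in
           one tick; zeroed probabilities give clean transits", {
  run <- long_run(model = "model1", p_spontaneous_reactivate = 1,
                  n_tfiis = 0L, n_ccr4 = 0L, seed = 3L)
  ev <- run$events
  bt <- which(ev$event == "backtrack" & ev$tick < max(ev$tick))
  for (i in bt) {
    pid <- ev$a1[i]
    nxt <- ev[ev$a1 == pid & ev$tick > ev$tick[i] &
                ev$event %in% c("spont_reactivate", "backtrack"), ][1, ]
    expect_identical(nxt$event, "spont_reactivate")
    expect_identical(nxt$tick, ev$tick[i] + 1L)
  }
  clean <- long_run(model = "model1", p_backtrack = 0, seed = 3L)
  expect_identical(count_events(clean, "backtrack"), 0L)
  m <- compute_metrics(clean$events, c(1L, 10000L), sim_config(
    base = unclass(default_config()), p_backtrack = 0))
  expect_equal(m$active_occupancy, m$total_occupancy)
})
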
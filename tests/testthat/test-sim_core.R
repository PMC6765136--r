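test_that("init_world places agents in their compartments", {
  cfg <- tiny_config(seed = 5L)
  w <- init_world(cfg)
  expect_identical(nrow(w$pol), cfg$n_polymerase)
  rp <- sqrt(w$pol$x^2 + w$pol$y^2 + w$pol$z^2)
  expect_true(all(rp <= cfg$nucleus_radius))
  tf <- w$fac[w$fac$type == "tfiis", ]
  expect_true(all(sqrt(tf$x^2 + tf$y^2 + tf$z^2) <= cfg$nucleus_radius))
  other <- w$fac[w$fac$type != "tfiis", ]
  expect_true(all(sqrt(other$x^2 + other$y^2 + other$z^2) <=
                    cfg$cytoplasm_radius))
  expect_identical(nrow(w$mrna), 0L)
  expect_true(all(is.na(w$occ)))
  expect_identical(w$tick, 0L)
  # knockout genotype = empty pool
  w0 <- init_world(apply_genotype(cfg, "xrn1d"))
  expect_identical(sum(w0$fac$type == "xrn1"), 0L)
  # same seed twice -> identical world
  expect_identical(init_world(cfg), init_world(cfg))
})

test_that("within_action_radius uses a closed ball", {
  expect_true(within_action_radius(c(0, 0, 0), c(0, 0, 0), 0.5))
  expect_true(within_action_radius(c(0, 0, 0), c(2, 0, 0), 2))   # boundary
  expect_false(within_action_radius(c(1, 0, 0), c(0, 1, 0), 1))  # sqrt(2)
})

test_that("move_agent takes bounded steps and respects confinement", {
  geom <- list(nucleus_radius = 5, cytoplasm_radius = 10)
  set.seed(2)
  for (k in 1:200) {
    p <- move_agent(c(0, 0, 0), 1, "nucleus", geom)
    expect_lt(abs(sqrt(sum(p^2)) - 1), 1e-9) # step length exactly 1
  }
  # reflection keeps a nuclear agent inside
  for (k in 1:200) {
    p0 <- c(4.9, 0, 0)
    p <- move_agent(p0, 1.5, "nucleus", geom)
    expect_lte(sqrt(sum(p^2)), 5 + 1e-9)
  }
  # cytoplasmic shell confinement
  for (k in 1:200) {
    p <- move_agent(c(5.2, 0, 0), 1.5, "cytoplasm", geom)
    r <- sqrt(sum(p^2))
    expect_gte(r, 5 - 1e-9); expect_lte(r, 10 + 1e-9)
  }
})

test_that("runs are deterministic given (config, seed)", {
  cfg <- tiny_config(seed = 31L)
  a <- run_sim(cfg); b <- run_sim(cfg)
  expect_identical(a$events, b$events)
  c2 <- run_sim(sim_config(base = unclass(cfg), seed = 32L))
  expect_false(identical(a$events, c2$events))
})

test_that("compartment and conservation invariants hold over a long run", {
  for (model in c("model1", "model2")) {
    cfg <- sim_config(base = unclass(default_config()), model = model,
                      burn_in_ticks = 0L, record_ticks = 10000L, seed = 13L)
    run <- run_sim(cfg, metrics = FALSE)
    ev <- run$events
    # conservation: every initiation is eventually balanced; the number of
    # polymerases on the gene never exceeds the pool and never goes negative
    on_gene <- cumsum((ev$event == "initiation") -
                        (ev$event %in% c("termination", "dropoff")))
    expect_true(all(on_gene >= 0))
    expect_true(all(on_gene <= cfg$n_polymerase))
    # mRNA pool: births minus deaths, never negative
    pool <- cumsum((ev$event == "mrna_birth") - (ev$event == "mrna_death"))
    expect_true(all(pool >= 0))
    # every death follows a birth of the same mRNA
    births <- ev[ev$event == "mrna_birth", ]
    deaths <- ev[ev$event == "mrna_death", ]
    expect_true(all(deaths$a1 %in% births$a1))
    expect_true(all(deaths$tick >= births$tick[match(deaths$a1, births$a1)]))
    # exports precede cytoplasmic engagement
    eng <- ev[ev$event == "decay_engage", ]
    exp_t <- ev$tick[ev$event == "export"][match(eng$a1,
      ev$a1[ev$event == "export"])]
    expect_true(all(eng$tick >= exp_t))
  }
})

test_that("steady state: terminations balance degradations in long WT runs", {
  # the net flux imbalance equals the pool change over the window; its
  # expectation is zero at steady state.  Averaging over replicate runs
  # estimates that expectation against the sampling-noise bound.
  imb <- pool <- numeric(0)
  for (s in 17:21) {
    cfg <- sim_config(base = unclass(default_config()), burn_in_ticks = 0L,
                      record_ticks = 10000L, seed = s)
    run <- run_sim(cfg, metrics = FALSE)
    ev <- run$events[run$events$tick > 5000L, ]
    imb <- c(imb, sum(ev$event == "termination") -
               sum(ev$event == "mrna_death"))
    pool <- c(pool, compute_metrics(run$events, c(5001L, 10000L),
                                    cfg)$mrna_mean)
  }
  expect_lte(abs(mean(imb)), 3 * sqrt(max(mean(pool), 1)))
})

test_that("degenerate configurations behave as specified", {
  # no polymerases: no occupancy, no mRNA
  cfg <- tiny_config(n_polymerase = 0L)
  run <- run_sim(cfg)
  expect_identical(nrow(run$events), 0L)
  expect_equal(run$metrics$total_occupancy, 0)
  expect_equal(run$metrics$mrna_mean, 0)
  # no decay route at all: the pool only grows (divergence is visible)
  cfg2 <- tiny_config(n_ccr4 = 0L, n_xrn1 = 0L, mrna_basal_decay = 0)
  run2 <- run_sim(cfg2, metrics = FALSE)
  expect_identical(sum(run2$events$event == "mrna_death"), 0L)
})

test_that("event log export writes tick/event/agent_ids", {
  run <- run_sim(det_config())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_event_log(run, path)
  back <- read.delim(path)
  expect_identical(names(back), c("tick", "event", "agent_ids"))
  expect_identical(nrow(back), nrow(run$events))
})
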
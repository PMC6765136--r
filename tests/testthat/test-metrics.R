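test_that("half_life_from_lifetimes matches the closed form", {
  expect_equal(half_life_from_lifetimes(rep(100, 50)), log(2) * 100)
  expect_equal(half_life_from_lifetimes(1), log(2))
  expect_true(is.na(half_life_from_lifetimes(numeric(0))))
  # geometric(p = 0.01) lifetimes: half-life ~ log(2)/(-log(1 - p)) = 68.97
  set.seed(11)
  lt <- rgeom(1e4, 0.01) + 1
  expect_equal(half_life_from_lifetimes(lt), log(2) / -log(0.99),
               tolerance = 0.05)
})

test_that("half_life_from_shutoff handles exact hits and interpolation", {
  tc <- data.frame(time = c(0, 10, 20), value = c(100, 50, 25))
  expect_equal(half_life_from_shutoff(tc), 10)
  tc2 <- data.frame(time = c(0, 10, 20), value = c(100, 80, 40))
  expect_equal(half_life_from_shutoff(tc2), 17.5)
  # re-based origin at minute 5: half of 90 reached exactly at t = 15
  tc3 <- data.frame(time = c(0, 5, 15), value = c(100, 90, 45))
  expect_equal(half_life_from_shutoff(tc3, start_from = 5), 10)
})

test_that("half_life_from_shutoff is scale-equivariant and errors sensibly", {
  set.seed(3)
  tc <- data.frame(time = c(0, 5, 10, 20, 30, 40),
                   value = 100 * 2^(-c(0, 5, 10, 20, 30, 40) / 13) *
                     exp(rnorm(6, 0, 0.02)))
  h1 <- half_life_from_shutoff(tc)
  tc$value <- tc$value * 7.3
  expect_equal(half_life_from_shutoff(tc), h1)
  flat <- data.frame(time = c(0, 10, 20), value = c(100, 95, 90))
  expect_error(half_life_from_shutoff(flat), "exceeds observation window")
  expect_error(half_life_from_shutoff(data.frame(time = 0, value = 1)),
               "at least 2")
  expect_error(half_life_from_shutoff(
    data.frame(time = c(0, 0, 5), value = c(3, 2, 1))), "strictly increasing")
})

test_that("speed_from_runoff recovers a retreating rectangular front", {
  # front retreats L/2 positions in T minutes: speed = L / (2T)
  L <- 8000; T <- 4
  pos <- seq(0, L, length.out = 401)
  prof <- rbind(
    data.frame(time = 0, position = pos, value = 1),
    data.frame(time = T, position = pos, value = as.numeric(pos >= L / 2))
  )
  expect_equal(speed_from_runoff(prof, L), L / (2 * T), tolerance = 0.01)
})

test_that("speed_from_runoff: zero change, complete clearance, exclusions", {
  pos <- seq(0, 100, by = 10)
  flat <- rbind(data.frame(time = 0, position = pos, value = 2),
                data.frame(time = 5, position = pos, value = 2))
  expect_equal(speed_from_runoff(flat, 100), 0)
  # complete clearance in the first interval; the later interval has weight 0
  prof <- rbind(data.frame(time = 0, position = pos, value = 1),
                data.frame(time = 2, position = pos, value = 0),
                data.frame(time = 4, position = pos, value = 0))
  expect_equal(speed_from_runoff(prof, 100), 50)
  # increasing signal -> warning and exclusion
  up <- rbind(data.frame(time = 0, position = pos, value = 1),
              data.frame(time = 2, position = pos, value = 2),
              data.frame(time = 4, position = pos, value = 0.5))
  expect_warning(v <- speed_from_runoff(up, 100), "increases")
  expect_true(is.finite(v))
  expect_error(speed_from_runoff(prof[prof$time == 0, ], 100), "2 time points")
})

test_that("speed_from_runoff recovers a programmed convoy velocity", {
  # constant-velocity retreat sampled at several times
  L <- 6000; v <- 900
  pos <- seq(0, L, length.out = 301)
  prof <- do.call(rbind, lapply(c(0, 1.5, 3), function(t)
    data.frame(time = t, position = pos, value = as.numeric(pos >= v * t))))
  expect_equal(speed_from_runoff(prof, L), v, tolerance = 0.05)
})

test_that("compute_metrics on a hand-written deterministic log", {
  # one polymerase: initiates at tick 1, advances 1 position/tick on a
  # 100-position gene -> termination at tick 100, cycle_ticks 100, speed 1
  ev <- data.frame(
    tick = c(1L, 100L, 100L, 150L, 260L),
    event = c("initiation", "termination", "mrna_birth", "export",
              "mrna_death"),
    code = NA_integer_, a1 = c(1L, 1L, 1L, 1L, 1L), a2 = NA_integer_
  )
  cfg <- sim_config(gene_length = 100L)
  m <- compute_metrics(ev, recording_window = c(1L, 300L), config = cfg)
  expect_equal(m$cycle_ticks, 100)
  expect_equal(m$speed, 1)
  expect_equal(m$half_life, log(2) * 160) # born tick 100, dies tick 260
  # end-of-tick states: on gene for ticks 1..99 (termination clears tick 100)
  expect_equal(m$total_occupancy, 99 / 300)
  expect_equal(m$active_occupancy, 99 / 300)
  expect_equal(m$backtracked_fraction, 0)
  expect_equal(m$mrna_mean, mean(c(rep(0, 99), rep(1, 160), rep(0, 41))))
})

test_that("undefined metrics are NA, not zero", {
  ev <- data.frame(tick = integer(0), event = character(0),
                   code = integer(0), a1 = integer(0), a2 = integer(0))
  m <- compute_metrics(ev, c(1L, 100L), sim_config())
  expect_true(is.na(m$speed) && is.na(m$cycle_ticks) && is.na(m$half_life))
  expect_equal(m$total_occupancy, 0)
  expect_error(compute_metrics(ev, c(10L, 5L), sim_config()), "empty")
})

test_that("shut-off and lifetime half-life estimators agree on a pure-death process", {
  # simulate exponential decay of a pool with per-tick hazard p, then apply
  # the shut-off estimator to the pool curve and the lifetime estimator to
  # the individual lifetimes
  set.seed(5)
  p <- 0.02
  lifetimes <- rgeom(4000, p) + 1
  h_lt <- half_life_from_lifetimes(lifetimes)
  tmax <- 250
  pool <- vapply(0:tmax, function(t) sum(lifetimes > t), numeric(1))
  h_so <- half_life_from_shutoff(data.frame(time = 0:tmax, value = pool))
  expect_equal(h_so, h_lt, tolerance = 0.1)
})

test_that("read_timecourse validates monotone times", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(time = c(0, 5, 10), value = c(3, 2, 1)), path,
            row.names = FALSE)
  tc <- read_timecourse(path)
  expect_equal(nrow(tc), 3L)
  write.csv(data.frame(time = c(0, 10, 5), value = c(3, 2, 1)), path,
            row.names = FALSE)
  expect_error(read_timecourse(path), "strictly increasing")
})
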
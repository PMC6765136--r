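# Shared tiny configurations for fast tests.  Defaults are scaled down from
# the calibrated configuration; tests that probe one mechanism override the
# relevant switches.

tiny_config <- function(...) {
  sim_config(burn_in_ticks = 100L, record_ticks = 400L, seed = 42L,
             base = unclass(default_config()), ...)
}

# deterministic scenario: no factors, certain initiation from anywhere in
# the nucleus, no backtracking, mRNA dies the tick it is born
det_config <- function(...) {
  sim_config(n_tfiis = 0L, n_ccr4 = 0L, n_xrn1 = 0L, p_init = 1,
             radius_promoter_contact = 1e3, p_backtrack = 0,
             p_inactivate = 0, mrna_basal_decay = 1, burn_in_ticks = 0L,
             record_ticks = 80L, seed = 7L, base = unclass(default_config()),
             ...)
}

count_events <- function(run, kind) sum(run$events$event == kind)
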
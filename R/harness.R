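## In-silico genetics harness: replicate runs per genotype, pooled-variance
## Student's t-tests, and sign-matrix construction.

.metric_rows <- c("total_mrna", "half_life", "total_rnapii", "active_rnapii",
                  "speed")
.metric_fields <- c(total_mrna = "mrna_mean", half_life = "half_life",
                    total_rnapii = "total_occupancy",
                    active_rnapii = "active_occupancy", speed = "speed")
.mutant_cols <- c("dst1d", "ccr4d", "xrn1d")

# disjoint seed blocks per genotype so wild-type and mutant samples are
# independent; replicate seeds are base seed + index within the block
.genotype_seed_offset <- c(wt = 0L, dst1d = 100000L, ccr4d = 200000L,
                           xrn1d = 300000L, custom = 400000L)

#' Run replicate simulations for one genotype
#'
#' Applies the genotype to the base configuration and performs `n_reps`
#' independent runs with derived seeds (base seed + a genotype-specific
#' block offset + the replicate index).  Replicates in which every metric
#' is undefined are recorded as missing with a warning.
#'
#' @param base_config a `sim_config` (wild-type parameterization).
#' @param genotype genotype name, see [apply_genotype()].
#' @param n_reps number of replicates (>= 2).
#' @param overrides extra config overrides (for `custom` genotypes).
#' @return A `metric_samples` object: data frame of one row per replicate
#'   (columns = the five matrix metrics plus auxiliaries), with attributes
#'   `genotype` and `seeds`.
#' @export
run_genotype <- function(base_config, genotype, n_reps = 100L,
                         overrides = list()) {
  if (n_reps < 2L) stop("n_reps must be >= 2")
  genotype <- sub("Δ$", "d", genotype)
  cfg <- apply_genotype(base_config, genotype, overrides)
  off <- .genotype_seed_offset[[genotype]]
  seeds <- base_config$seed + off + seq_len(n_reps)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    m <- run_sim(sim_config(seed = seeds[r], base = cfg))$metrics
    rows[[r]] <- data.frame(
      replicate = r, seed = seeds[r],
      total_mrna = m$mrna_mean, half_life = m$half_life,
      total_rnapii = m$total_occupancy, active_rnapii = m$active_occupancy,
      speed = m$speed, cycle_ticks = m$cycle_ticks,
      backtracked_fraction = m$backtracked_fraction
    )
  }
  out <- do.call(rbind, rows)
  all_na <- apply(out[, .metric_rows], 1, function(x) all(is.na(x)))
  if (any(all_na))
    warning(sum(all_na), " replicate(s) with all metrics undefined (",
            genotype, ")")
  structure(out, genotype = genotype, seeds = seeds,
            class = c("metric_samples", "data.frame"))
}

#' Pooled-variance two-sample Student's t-test
#'
#' The classical equal-variance Student's t statistic with a two-sided
#' p-value from the t distribution on `n_x + n_y - 2` degrees of freedom.
#' Missing values are dropped.  A zero pooled variance yields `t = 0,
#' p = 1` for equal means and a zero-limit p for unequal means.
#'
#' @param x,y numeric samples (>= 2 non-missing values each).
#' @return List with `t`, `p`, `df`, `mean_x`, `mean_y`.
#' @export
two_sample_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("need >= 2 non-missing values per sample")
  df <- nx + ny - 2L
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  dm <- mean(x) - mean(y)
  if (sp2 == 0) {
    t <- if (dm == 0) 0 else sign(dm) * Inf
    p <- if (dm == 0) 1 else 0
  } else {
    t <- dm / sqrt(sp2 * (1 / nx + 1 / ny))
    p <- 2 * stats::pt(-abs(t), df)
  }
  list(t = t, p = p, df = df, mean_x = mean(x), mean_y = mean(y))
}

#' Build the 5 x 3 sign matrix from replicate samples
#'
#' For each of the five parameters (total mRNA, mRNA half-life, total
#' RNAPII, active RNAPII, RNAPII speed) and each mutant, the entry is 0 if
#' the mutant is not significantly different from wild type by a
#' pooled-variance Student's t-test at level `alpha`, and otherwise the
#' sign of the mutant-minus-wild-type mean difference.  If fewer than two
#' non-missing values remain in either group, or at least half the mutant
#' replicates are missing, the entry is 0 with a warning (insufficient
#' evidence).
#'
#' @param wt `metric_samples` for the wild type.
#' @param mutants named list of `metric_samples`, one per mutant column
#'   (defaults order: dst1d, ccr4d, xrn1d).
#' @param alpha significance level in (0, 1).
#' @return A `sign_matrix`: integer matrix with parameter rows and mutant
#'   columns, entries in {-1, 0, +1}.
#' @export
build_sign_matrix <- function(wt, mutants, alpha = 0.05) {
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)")
  if (is.null(names(mutants)) || any(!nzchar(names(mutants))))
    stop("mutants must be a named list")
  M <- matrix(0L, nrow = length(.metric_rows), ncol = length(mutants),
              dimnames = list(.metric_rows, names(mutants)))
  for (mut in names(mutants)) {
    for (met in .metric_rows) {
      xv <- mutants[[mut]][[met]]
      yv <- wt[[met]]
      if (sum(is.na(xv)) >= length(xv) / 2) {
        warning("metric ", met, " missing in >= half the ", mut,
                " replicates; entry set to 0")
        next
      }
      if (sum(!is.na(xv)) < 2L || sum(!is.na(yv)) < 2L) {
        warning("insufficient data for ", met, " in ", mut, "; entry set to 0")
        next
      }
      tt <- two_sample_t(xv, yv)
      if (tt$p < alpha && alpha > 0)
        M[met, mut] <- as.integer(sign(tt$mean_x - tt$mean_y))
    }
  }
  structure(M, class = c("sign_matrix", class(M)))
}

#' Run the full four-genotype harness and build its sign matrix
#'
#' Convenience wrapper: runs wt, dst1d, ccr4d and xrn1d with `n_reps`
#' replicates each under `base_config` and returns the resulting sign
#' matrix (plus the samples, as an attribute).
#'
#' @inheritParams run_genotype
#' @param alpha significance level for [build_sign_matrix()].
#' @return A `sign_matrix` with attribute `samples`.
#' @export
harness_sign_matrix <- function(base_config, n_reps = 100L, alpha = 0.05) {
  wt <- run_genotype(base_config, "wt", n_reps)
  muts <- lapply(setNames(.mutant_cols, .mutant_cols),
                 function(g) run_genotype(base_config, g, n_reps))
  sm <- build_sign_matrix(wt, muts, alpha)
  attr(sm, "samples") <- c(list(wt = wt), muts)
  sm
}

#' Write harness samples as TSV
#'
#' One row per (genotype, replicate, metric), the harness output format.
#'
#' @param samples named list of `metric_samples`.
#' @param path output path.
#' @export
write_harness_tsv <- function(samples, path) {
  rows <- lapply(names(samples), function(g) {
    s <- samples[[g]]
    do.call(rbind, lapply(.metric_rows, function(met) {
      data.frame(genotype = g, replicate = s$replicate, metric = met,
                 value = s[[met]])
    }))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
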
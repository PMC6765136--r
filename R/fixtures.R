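## Synthetic fixture generation with embedded ground truth.  Fixtures stand
## in for experimental shut-off and run-off tables; each generated file is
## accompanied by a JSON sidecar recording the programmed truth.

#' Generate synthetic fixtures with known ground truth
#'
#' * `shutoff_timecourse`: an exponential-decay shut-off time course with a
#'   programmed half-life (plus multiplicative noise), sampled at the assay
#'   time points 0, 5, 10, 20, 30, 40, 50, 60 min.
#' * `runoff_profiles`: spatial occupancy profiles of a polymerase convoy
#'   retreating at a programmed constant velocity, at shut-off times
#'   0, 2, 3, 4 min.
#' * `sign_matrices`: a pair of 5 x 3 sign matrices constructed by
#'   inverting the scoring rule to a designed hit/penalty composition.
#'
#' A sidecar `<kind>_truth.json` records the programmed quantities.
#'
#' @param kind one of `"shutoff_timecourse"`, `"runoff_profiles"`,
#'   `"sign_matrices"`.
#' @param seed RNG seed.
#' @param dir output directory (created if needed).
#' @param half_life programmed half-life, minutes (shut-off fixture).
#' @param noise_sd multiplicative log-normal noise sd (shut-off fixture).
#' @param velocity programmed retreat velocity, positions/min (run-off).
#' @param gene_length gene length, positions (run-off).
#' @param hits,opposite designed composition (sign-matrix fixture;
#'   remaining cells are neutral mismatches).
#' @return Named character vector of the files written.
#' @export
generate_fixtures <- function(kind = c("shutoff_timecourse",
                                       "runoff_profiles", "sign_matrices"),
                              seed = 1L, dir = tempdir(),
                              half_life = 12, noise_sd = 0,
                              velocity = 1000, gene_length = 8000,
                              hits = 7L, opposite = 0L) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  truth_path <- file.path(dir, paste0(kind, "_truth.json"))
  if (kind == "shutoff_timecourse") {
    times <- c(0, 5, 10, 20, 30, 40, 50, 60)
    values <- 100 * 2^(-times / half_life)
    if (noise_sd > 0) values <- values * exp(rnorm(length(values), 0, noise_sd))
    path <- file.path(dir, "shutoff_timecourse.csv")
    utils::write.csv(data.frame(time = times, value = values), path,
                     row.names = FALSE)
    jsonlite::write_json(list(half_life = half_life, noise_sd = noise_sd),
                         truth_path, auto_unbox = TRUE, digits = NA)
    c(data = path, truth = truth_path)
  } else if (kind == "runoff_profiles") {
    times <- c(0, 2, 3, 4)
    pos <- seq(0, gene_length, length.out = 81)
    rows <- do.call(rbind, lapply(times, function(t) {
      front <- velocity * t # polymerases cleared up to this coordinate
      data.frame(time = t, position = pos,
                 value = ifelse(pos >= front, 1, 0))
    }))
    path <- file.path(dir, "runoff_profiles.csv")
    utils::write.csv(rows, path, row.names = FALSE)
    jsonlite::write_json(list(velocity = velocity, gene_length = gene_length),
                         truth_path, auto_unbox = TRUE, digits = NA)
    c(data = path, truth = truth_path)
  } else {
    n <- 15L
    if (hits + opposite > n) stop("hits + opposite cannot exceed 15 cells")
    ref <- invivo_reference()
    other <- unclass(ref)
    nz <- which(ref != 0L)
    if (opposite > length(nz))
      stop("not enough nonzero reference cells for ", opposite, " penalties")
    flip_opp <- sample(nz, opposite)
    flip_neu <- sample(setdiff(seq_len(n), flip_opp), n - hits - opposite)
    for (i in flip_opp) other[i] <- -ref[i]
    for (i in flip_neu)
      other[i] <- if (ref[i] == 0L) 1L else 0L
    p1 <- file.path(dir, "sign_matrix_a.tsv")
    p2 <- file.path(dir, "sign_matrix_b.tsv")
    write_sign_matrix(ref, p1)
    write_sign_matrix(structure(other, class = class(ref)), p2)
    jsonlite::write_json(list(score = hits - opposite, hits = hits,
                              opposite = opposite), truth_path,
                         auto_unbox = TRUE, digits = NA)
    c(a = p1, b = p2, truth = truth_path)
  }
}
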
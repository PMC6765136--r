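## Pure-R reference engine: world construction and spatial primitives.
## The C++ engine (src/engine.cpp) is the production path; this engine
## implements the identical rule set and phase order and serves as its
## independent cross-check (deterministic scenarios yield identical logs).

#' Initialize a simulation world
#'
#' Places all agents uniformly at random inside their permitted compartment
#' (polymerases and TFIIS in the nucleus; Xrn1 and Ccr4-Not anywhere in the
#' cell), leaves the gene unoccupied and the mRNA pool empty, and seeds R's
#' RNG from `config$seed`.
#'
#' @param config a validated [sim_config()].
#' @return A `sim_world` list with components `tick`, `pol`, `fac`, `mrna`,
#'   `occ` (gene occupancy map) and `events` (append-only log buffer).
#' @export
init_world <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  nP <- config$n_polymerase
  pol <- data.frame(
    id = seq_len(nP), x = 0, y = 0, z = 0,
    phase = rep("free", nP), cls = rep("A0", nP),
    gene_pos = 0L, immune = FALSE, rider = NA_integer_,
    stringsAsFactors = FALSE
  )
  if (nP > 0) {
    p <- .runif_ball(nP, config$nucleus_radius)
    pol$x <- p[, 1]; pol$y <- p[, 2]; pol$z <- p[, 3]
  }
  types <- c(rep("tfiis", config$n_tfiis), rep("ccr4", config$n_ccr4),
             rep("xrn1", config$n_xrn1))
  nF <- length(types)
  fac <- data.frame(
    id = nP + seq_len(nF), type = types, x = numeric(nF), y = numeric(nF),
    z = numeric(nF), busy = integer(nF), stringsAsFactors = FALSE
  )
  for (i in seq_len(nF)) {
    R <- if (types[i] == "tfiis") config$nucleus_radius else config$cytoplasm_radius
    p <- .runif_ball(1, R)
    fac$x[i] <- p[1]; fac$y[i] <- p[2]; fac$z[i] <- p[3]
  }
  mrna <- data.frame(
    id = integer(0), x = numeric(0), y = numeric(0), z = numeric(0),
    compartment = character(0), birth = integer(0), engaged_by = integer(0),
    progress = integer(0), imprint = integer(0), alive = logical(0),
    stringsAsFactors = FALSE
  )
  structure(list(
    tick = 0L, config = config, pol = pol, fac = fac, mrna = mrna,
    occ = rep(NA_integer_, config$gene_length), events = list()
  ), class = "sim_world")
}

# n uniform points in a ball of radius R (rejection sampling, matching the
# C++ engine's law though not its RNG stream)
.runif_ball <- function(n, R) {
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    repeat {
      p <- runif(3, -R, R)
      if (sqrt(sum(p^2)) <= R) break
    }
    out[i, ] <- p
  }
  out
}

# one isotropic random step of length s
.rand_step <- function(s) {
  zc <- 2 * runif(1) - 1
  phi <- 2 * pi * runif(1)
  rxy <- sqrt(max(0, 1 - zc^2))
  c(s * rxy * cos(phi), s * rxy * sin(phi), s * zc)
}

.reflect_outer <- function(p, R) {
  r <- sqrt(sum(p^2))
  if (r > R) {
    rr <- 2 * R - r
    if (rr < 0) rr <- R
    p <- p * if (r > 0) rr / r else 0
  }
  p
}

.reflect_inner <- function(p, Rin, Rout) {
  r <- sqrt(sum(p^2))
  if (r < Rin) {
    rr <- min(2 * Rin - r, Rout)
    if (r > 1e-12) p <- p * rr / r else p <- c(Rin, 0, 0)
  }
  p
}

#' Proximity test between two positions
#'
#' Contact is a closed ball: a distance exactly equal to the radius counts
#' as within reach (inclusive tie-break, for reproducibility).
#'
#' @param a,b numeric length-3 positions.
#' @param radius action radius (length units).
#' @return `TRUE` iff the Euclidean distance is `<= radius`.
#' @export
within_action_radius <- function(a, b, radius) {
  sqrt(sum((a - b)^2)) <= radius
}

#' Displace one mobile agent by a bounded random step
#'
#' Applies an isotropic random step of fixed length and reflects the
#' position at the agent's compartment boundary so confinement invariants
#' hold: `"nucleus"` keeps the agent inside the nuclear sphere, `"cell"`
#' inside the outer sphere, `"cytoplasm"` inside the shell between the two.
#'
#' @param position numeric length-3 current position.
#' @param step_length step length for the agent's class.
#' @param confinement one of `"nucleus"`, `"cell"`, `"cytoplasm"`.
#' @param geometry list with `nucleus_radius` and `cytoplasm_radius`.
#' @return The new length-3 position.
#' @export
move_agent <- function(position, step_length, confinement, geometry) {
  p <- position + .rand_step(step_length)
  switch(confinement,
    nucleus = .reflect_outer(p, geometry$nucleus_radius),
    cell = .reflect_outer(p, geometry$cytoplasm_radius),
    cytoplasm = .reflect_outer(
      .reflect_inner(p, geometry$nucleus_radius, geometry$cytoplasm_radius),
      geometry$cytoplasm_radius),
    stop("unknown confinement: ", confinement)
  )
}
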
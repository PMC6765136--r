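#' @useDynLib txdecay, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats pt rnorm runif sd setNames
#' @importFrom utils read.delim write.table modifyList
"_PACKAGE"

## All tunable constants of one simulation run live in a flat named list of
## class "sim_config".  Field names are exactly the keys accepted in config
## files; unknown keys are an error.

.config_fields <- list(
  # agent counts (a genotype knockout is purely a zeroed count)
  n_polymerase = 6L, n_tfiis = 2L, n_ccr4 = 3L, n_xrn1 = 5L,
  # gene and geometry (two concentric spheres centred at the origin; the
  # gene sits at the origin, inside the nucleus)
  gene_length = 30L, nucleus_radius = 5, cytoplasm_radius = 10,
  dimensions = 3L,
  # action radii (closed balls: distance <= radius counts as contact)
  radius_tfiis = 2, radius_ccr4 = 2, radius_promoter_contact = 2.5,
  radius_xrn1_promoter = 5, radius_decay = 2,
  # per-class random-walk step lengths
  step_polymerase = 1, step_tfiis = 1, step_ccr4 = 1, step_xrn1 = 1,
  step_mrna = 1,
  # initiation
  p_init = 0.2, xrn1_boost = 1,
  # elongation state machine
  p_backtrack = 0.02,              # model 1: elongating -> backtracked
  p_inactivate = 0.02,             # model 2: A0 -> I
  ac_inactivate_scale = 0.1,       # model 2: A_c inactivation multiplier
  p_spontaneous_reactivate = 0.02, # backtracked -> elongating, unassisted
  p_dropoff = 0.1,                 # model 2: I_b -> off the gene
  step_advance = 1L,               # base positions per tick (A0, model 1)
  ax_speed_mult = 2, ac_speed_mult = 1,
  # mRNA lifecycle
  mrna_basal_decay = 0.002, degradation_ticks = 20L,
  export_rule = "crossing",
  # variant switches (the 2 x 4 x 2 grid plus model 2)
  model = "model1",
  ccr4_mode = "reactivate",        # prevent | reactivate | recruit_tfiis | none
  xrn1_feedback = TRUE,
  imprinting = TRUE,
  model2_rate_boost = TRUE,        # model 2 keeps the initiation-rate boost
  # schedule
  burn_in_ticks = 2000L, record_ticks = 3000L,
  seed = 1L
)

.int_fields <- c("n_polymerase", "n_tfiis", "n_ccr4", "n_xrn1", "gene_length",
                 "dimensions", "step_advance", "degradation_ticks",
                 "burn_in_ticks", "record_ticks", "seed")
.prob_fields <- c("p_init", "p_backtrack", "p_inactivate",
                  "p_spontaneous_reactivate", "p_dropoff", "mrna_basal_decay")
.flag_fields <- c("xrn1_feedback", "imprinting", "model2_rate_boost")

#' Build a simulation configuration
#'
#' Creates the full set of tunable constants for one run of the multi-agent
#' model: agent counts, compartment geometry, action radii, per-tick
#' probabilities, model-variant switches, genotype-relevant pool sizes and
#' the RNG seed.  Defaults are the calibrated wild-type values shipped in
#' `inst/extdata/default_config.json` (see [default_config()]); any field
#' can be overridden by name.
#'
#' @param ... named overrides of configuration fields. Unknown names are an
#'   error.
#' @param base a `sim_config` (or plain named list) to start from; defaults
#'   to the built-in field defaults.
#' @return A validated object of class `sim_config` (a flat named list).
#' @examples
#' cfg <- sim_config(n_xrn1 = 0L, model = "model2")  # an in-silico xrn1 null
#' cfg$n_xrn1
#' @export
sim_config <- function(..., base = NULL) {
  cfg <- .config_fields
  if (!is.null(base)) {
    base <- unclass(base)
    bad <- setdiff(names(base), names(.config_fields))
    if (length(bad)) stop("unknown configuration field(s): ",
                          paste(bad, collapse = ", "))
    cfg <- modifyList(cfg, base)
  }
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(!nzchar(names(ov))))
      stop("configuration overrides must be named")
    bad <- setdiff(names(ov), names(.config_fields))
    if (length(bad)) stop("unknown configuration field(s): ",
                          paste(bad, collapse = ", "))
    cfg <- modifyList(cfg, ov)
  }
  for (f in .int_fields) cfg[[f]] <- as.integer(cfg[[f]])
  structure(cfg, class = "sim_config")
}

#' Validate a simulation configuration
#'
#' Checks every invariant of the configuration contract: probabilities in
#' \[0, 1\], non-negative counts, `gene_length >= 2`, a nucleus strictly
#' inside the cytoplasm, and legal variant switches.  Errors name the
#' offending field.
#'
#' @param config a `sim_config`.
#' @return `config`, invisibly, if valid.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("config must be created with sim_config()")
  for (f in .prob_fields) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("configuration error in field '", f, "': must be a probability in [0, 1]")
  }
  for (f in c("n_polymerase", "n_tfiis", "n_ccr4", "n_xrn1")) {
    v <- config[[f]]
    if (is.na(v) || v < 0L)
      stop("configuration error in field '", f, "': count must be >= 0")
  }
  if (is.na(config$gene_length) || config$gene_length < 2L)
    stop("configuration error in field 'gene_length': must be >= 2")
  if (!identical(config$dimensions, 3L))
    stop("configuration error in field 'dimensions': only 3 is supported")
  if (!(config$nucleus_radius > 0) ||
      !(config$cytoplasm_radius > config$nucleus_radius))
    stop("configuration error in field 'nucleus_radius': ",
         "need 0 < nucleus_radius < cytoplasm_radius")
  for (f in c("radius_tfiis", "radius_ccr4", "radius_promoter_contact",
              "radius_xrn1_promoter", "radius_decay", "step_polymerase",
              "step_tfiis", "step_ccr4", "step_xrn1", "step_mrna",
              "xrn1_boost", "ax_speed_mult", "ac_speed_mult",
              "ac_inactivate_scale"))
    if (!is.numeric(config[[f]]) || is.na(config[[f]]) || config[[f]] < 0)
      stop("configuration error in field '", f, "': must be >= 0")
  if (!config$model %in% c("model1", "model2"))
    stop("configuration error in field 'model': must be 'model1' or 'model2'")
  if (!config$ccr4_mode %in% c("prevent", "reactivate", "recruit_tfiis", "none"))
    stop("configuration error in field 'ccr4_mode'")
  if (!identical(config$export_rule, "crossing"))
    stop("configuration error in field 'export_rule': only 'crossing' is supported")
  for (f in .flag_fields)
    if (!is.logical(config[[f]]) || is.na(config[[f]]))
      stop("configuration error in field '", f, "': must be TRUE or FALSE")
  if (config$step_advance < 1L)
    stop("configuration error in field 'step_advance': must be >= 1")
  if (config$degradation_ticks < 1L)
    stop("configuration error in field 'degradation_ticks': must be >= 1")
  if (config$burn_in_ticks < 0L)
    stop("configuration error in field 'burn_in_ticks': must be >= 0")
  if (config$record_ticks < 1L)
    stop("configuration error in field 'record_ticks': empty observation window")
  invisible(config)
}

#' Calibrated default configuration
#'
#' Loads the calibrated wild-type defaults shipped with the package
#' (`inst/extdata/default_config.json`), the configuration selected by the
#' documented calibration procedure against the text-derived in-vivo sign
#' constraints, and applies optional overrides.
#'
#' @inheritParams sim_config
#' @return A validated `sim_config`.
#' @export
default_config <- function(...) {
  path <- system.file("extdata", "default_config.json", package = "txdecay")
  base <- read_config(path)
  sim_config(..., base = base)
}

#' Read / write a configuration file
#'
#' Configuration files are flat JSON objects whose keys exactly match the
#' `sim_config` field names; unknown keys are an error.
#'
#' @param path file path.
#' @return `read_config()` returns a validated `sim_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- sim_config(base = raw)
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @param config a `sim_config` to serialize.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$model,
      " | ccr4_mode=", x$ccr4_mode,
      " | xrn1_feedback=", x$xrn1_feedback,
      " | imprinting=", x$imprinting, "\n", sep = "")
  cat("  agents: ", x$n_polymerase, " RNAPII, ", x$n_tfiis, " TFIIS, ",
      x$n_ccr4, " Ccr4-Not, ", x$n_xrn1, " Xrn1\n", sep = "")
  cat("  gene length ", x$gene_length, ", nucleus r=", x$nucleus_radius,
      ", cytoplasm r=", x$cytoplasm_radius, "\n", sep = "")
  cat("  schedule: ", x$burn_in_ticks, " burn-in + ", x$record_ticks,
      " recorded ticks, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

## ---- genotypes --------------------------------------------------------

.genotypes <- list(
  wt    = list(),
  dst1d = list(n_tfiis = 0L),
  ccr4d = list(n_ccr4 = 0L),
  xrn1d = list(n_xrn1 = 0L)
)

#' Apply an in-silico genotype to a configuration
#'
#' Knockouts are expressed purely as zeroed agent counts: `dst1d` sets
#' `n_tfiis = 0`, `ccr4d` sets `n_ccr4 = 0`, `xrn1d` sets `n_xrn1 = 0`.
#' A `custom` genotype applies arbitrary field overrides.
#'
#' @param config a `sim_config`.
#' @param genotype one of `"wt"`, `"dst1d"`, `"ccr4d"`, `"xrn1d"`,
#'   `"custom"`.  Unicode delta spellings (e.g. `"xrn1Δ"`) are accepted.
#' @param overrides named list of field overrides (required for `custom`).
#' @return The modified, validated `sim_config`.
#' @export
apply_genotype <- function(config, genotype, overrides = list()) {
  genotype <- sub("Δ$", "d", genotype)
  if (identical(genotype, "custom")) {
    ov <- overrides
  } else {
    if (!genotype %in% names(.genotypes))
      stop("unknown genotype: ", genotype, " (use wt/dst1d/ccr4d/xrn1d/custom)")
    ov <- modifyList(.genotypes[[genotype]], overrides)
  }
  cfg <- sim_config(base = modifyList(unclass(config), ov))
  validate_config(cfg)
  cfg
}

#' Canonical genotype names
#' @return Character vector of the built-in genotype names.
#' @export
genotype_names <- function() names(.genotypes)
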
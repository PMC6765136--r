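## Pure-R reference engine: the biological rule set.  Each phase function
## takes (world, config) and returns the updated world, appending to the
## event log.  Rules, phase order and tie-breaks mirror src/engine.cpp.

.EV <- c(initiation = 1L, class_ax = 2L, backtrack = 3L, inactivate = 4L,
         tfiis_rescue = 5L, tfiis_rescue_i = 6L, ccr4_reactivate = 7L,
         ccr4_prevent = 8L, ccr4_recruit = 9L, ccr4_enhance = 10L,
         ccr4_rescue = 11L, spont_reactivate = 12L, dropoff = 13L,
         termination = 14L, mrna_birth = 15L, export = 16L,
         decay_engage = 17L, degradation_complete = 18L, basal_decay = 19L,
         mrna_death = 20L, imprint_bind = 21L, imprint_transfer = 22L)

#' Event code table
#'
#' Maps the integer event codes used in event logs to event names.
#' @return Named integer vector.
#' @export
event_codes <- function() .EV

.log_ev <- function(world, code, a1, a2 = 0L) {
  world$events[[length(world$events) + 1L]] <-
    c(world$tick, .EV[[code]], as.integer(a1), as.integer(a2))
  world
}

.pol_pos <- function(world, i) c(world$pol$x[i], world$pol$y[i], world$pol$z[i])
.fac_pos <- function(world, i) c(world$fac$x[i], world$fac$y[i], world$fac$z[i])

# free nuclear Xrn1 molecules within promoter reach (the initiation signal)
.n_xrn1_near <- function(world, config) {
  f <- world$fac
  if (!nrow(f)) return(0L)
  sel <- f$type == "xrn1" & f$busy == 0L
  if (!any(sel)) return(0L)
  r <- sqrt(f$x[sel]^2 + f$y[sel]^2 + f$z[sel]^2)
  sum(r <= config$nucleus_radius & r <= config$radius_xrn1_promoter)
}

#' @rdname step_world
#' @export
attempt_initiation <- function(world, config) {
  if (!is.na(world$occ[1])) return(world)    # position 1 occupied: exclusion
  free <- which(world$pol$phase == "free")
  if (!length(free)) return(world)
  d <- sqrt(world$pol$x[free]^2 + world$pol$y[free]^2 + world$pol$z[free]^2)
  ok <- d <= config$radius_promoter_contact
  if (!any(ok)) return(world)
  cand <- free[ok][which.min(d[ok])]         # nearest; ties -> lowest id
  n_near <- .n_xrn1_near(world, config)
  model2 <- config$model == "model2"
  p <- config$p_init
  if (config$xrn1_feedback && (!model2 || config$model2_rate_boost))
    p <- min(1, config$p_init * (1 + config$xrn1_boost * n_near))
  if (runif(1) < p) {
    world$pol$phase[cand] <- "gene"
    world$pol$gene_pos[cand] <- 1L
    world$pol$x[cand] <- 0; world$pol$y[cand] <- 0; world$pol$z[cand] <- 0
    world$pol$immune[cand] <- FALSE
    world$pol$cls[cand] <- "A0"
    world$occ[1] <- cand
    world <- .log_ev(world, "initiation", cand)
    if (model2 && config$xrn1_feedback && n_near >= 1L) {
      world$pol$cls[cand] <- "Ax"
      world <- .log_ev(world, "class_ax", cand)
    }
  }
  world
}

# advance polymerase i by up to `by` positions, blocked by the pol ahead
.advance <- function(world, i, by, L) {
  target <- min(L, world$pol$gene_pos[i] + by)
  np <- world$pol$gene_pos[i]
  for (q in seq(world$pol$gene_pos[i] + 1L, length.out = max(0L, target - world$pol$gene_pos[i]))) {
    if (!is.na(world$occ[q])) break
    np <- q
  }
  if (np != world$pol$gene_pos[i]) {
    world$occ[world$pol$gene_pos[i]] <- NA_integer_
    world$occ[np] <- i
    world$pol$gene_pos[i] <- np
  }
  world
}

#' @rdname step_world
#' @export
elongation_update <- function(world, config) {
  L <- config$gene_length
  model2 <- config$model == "model2"
  adv <- config$step_advance
  adv_ax <- max(1L, as.integer(round(adv * config$ax_speed_mult)))
  adv_ac <- max(1L, as.integer(round(adv * config$ac_speed_mult)))
  for (posn in seq(L, 1L)) {
    i <- world$occ[posn]
    if (is.na(i)) next
    cls <- world$pol$cls[i]
    if (!model2) {
      if (cls == "A0") {
        if (!world$pol$immune[i] && runif(1) < config$p_backtrack) {
          world$pol$cls[i] <- "Ib"
          world <- .log_ev(world, "backtrack", i)
        } else world <- .advance(world, i, adv, L)
      } else if (runif(1) < config$p_spontaneous_reactivate) {
        world$pol$cls[i] <- "A0"
        world <- .log_ev(world, "spont_reactivate", i)
      }
    } else {
      if (cls == "Ax") {
        world <- .advance(world, i, adv_ax, L)
      } else if (cls == "Ac") {
        if (runif(1) < config$p_inactivate * config$ac_inactivate_scale) {
          world$pol$cls[i] <- "I"; world <- .log_ev(world, "inactivate", i)
        } else world <- .advance(world, i, adv_ac, L)
      } else if (cls == "A0") {
        if (runif(1) < config$p_inactivate) {
          world$pol$cls[i] <- "I"; world <- .log_ev(world, "inactivate", i)
        } else world <- .advance(world, i, adv, L)
      } else if (cls == "I") {
        world$pol$cls[i] <- "Ib"; world <- .log_ev(world, "backtrack", i)
      } else { # Ib
        if (runif(1) < config$p_spontaneous_reactivate) {
          world$pol$cls[i] <- "A0"; world <- .log_ev(world, "spont_reactivate", i)
        } else if (runif(1) < config$p_dropoff) {
          world$occ[world$pol$gene_pos[i]] <- NA_integer_
          world$pol$phase[i] <- "free"; world$pol$gene_pos[i] <- 0L
          world$pol$cls[i] <- "A0"
          world$pol$x[i] <- 0; world$pol$y[i] <- 0; world$pol$z[i] <- 0
          rid <- world$pol$rider[i]
          if (!is.na(rid)) { world$fac$busy[rid] <- 0L; world$pol$rider[i] <- NA_integer_ }
          world <- .log_ev(world, "dropoff", i)
        }
      }
    }
  }
  world
}

.bind_rider <- function(world, pi, ci, config) {
  if (config$imprinting && is.na(world$pol$rider[pi])) {
    world$pol$rider[pi] <- ci
    world$fac$busy[ci] <- 1L
    world$fac$x[ci] <- 0; world$fac$y[ci] <- 0; world$fac$z[ci] <- 0
    world <- .log_ev(world, "imprint_bind", pi, world$fac$id[ci])
  }
  world
}

#' @rdname step_world
#' @export
ccr4_action <- function(world, config) {
  model2 <- config$model == "model2"
  Rn <- config$nucleus_radius
  for (ci in which(world$fac$type == "ccr4" & world$fac$busy == 0L)) {
    p <- .fac_pos(world, ci)
    if (sqrt(sum(p^2)) > Rn) next
    if (!within_action_radius(p, c(0, 0, 0), config$radius_ccr4)) next
    target <- NA_integer_
    for (i in which(world$pol$phase == "gene")) {
      cls <- world$pol$cls[i]
      hit <- if (!model2) {
        switch(config$ccr4_mode,
               prevent = cls == "A0" && !world$pol$immune[i],
               reactivate = cls == "Ib",
               recruit_tfiis = cls == "Ib",
               none = FALSE)
      } else cls %in% c("A0", "I")
      if (hit) { target <- i; break }
    }
    if (is.na(target)) {
      # imprinting is a standing property of Ccr4-Not, independent of the
      # elongation-feedback mode: on contact it can bind any on-gene
      # polymerase without a rider and ride to termination
      if (config$imprinting) {
        cand <- which(world$pol$phase == "gene" & is.na(world$pol$rider))
        if (length(cand)) world <- .bind_rider(world, cand[1], ci, config)
      }
      next
    }
    if (!model2) {
      if (config$ccr4_mode == "prevent") {
        world$pol$immune[target] <- TRUE
        world <- .log_ev(world, "ccr4_prevent", target, world$fac$id[ci])
        world <- .bind_rider(world, target, ci, config)
      } else if (config$ccr4_mode == "reactivate") {
        world$pol$cls[target] <- "A0"
        world <- .log_ev(world, "ccr4_reactivate", target, world$fac$id[ci])
        world <- .bind_rider(world, target, ci, config)
      } else { # recruit_tfiis
        ti <- which(world$fac$type == "tfiis" & world$fac$busy == 0L)[1]
        if (!is.na(ti)) {
          world$fac$x[ti] <- 0; world$fac$y[ti] <- 0; world$fac$z[ti] <- 0
          world$pol$cls[target] <- "A0"
          world <- .log_ev(world, "ccr4_recruit", target, world$fac$id[ci])
          world <- .log_ev(world, "tfiis_rescue", target, world$fac$id[ti])
          world <- .bind_rider(world, target, ci, config)
        }
      }
    } else {
      was_i <- world$pol$cls[target] == "I"
      world$pol$cls[target] <- "Ac"
      world <- .log_ev(world, if (was_i) "ccr4_rescue" else "ccr4_enhance",
                       target, world$fac$id[ci])
      world <- .bind_rider(world, target, ci, config)
    }
  }
  world
}

#' @rdname step_world
#' @export
tfiis_action <- function(world, config) {
  model2 <- config$model == "model2"
  for (ti in which(world$fac$type == "tfiis" & world$fac$busy == 0L)) {
    if (!within_action_radius(.fac_pos(world, ti), c(0, 0, 0),
                              config$radius_tfiis)) next
    target <- NA_integer_; from_i <- FALSE
    for (i in which(world$pol$phase == "gene")) {
      if (world$pol$cls[i] == "Ib") { target <- i; from_i <- FALSE; break }
      if (model2 && world$pol$cls[i] == "I") { target <- i; from_i <- TRUE; break }
    }
    if (is.na(target)) next
    world$pol$cls[target] <- "A0"
    world <- .log_ev(world, if (from_i) "tfiis_rescue_i" else "tfiis_rescue",
                     target, world$fac$id[ti])
  }
  world
}

#' @rdname step_world
#' @export
terminate_pols <- function(world, config) {
  L <- config$gene_length
  i <- world$occ[L]
  if (is.na(i)) return(world)
  if (!world$pol$cls[i] %in% c("A0", "Ax", "Ac")) return(world)
  world$occ[L] <- NA_integer_
  world$pol$phase[i] <- "free"; world$pol$gene_pos[i] <- 0L
  world$pol$x[i] <- 0; world$pol$y[i] <- 0; world$pol$z[i] <- 0
  world <- .log_ev(world, "termination", i)
  mid <- nrow(world$mrna) + 1L
  imprint <- NA_integer_
  rid <- world$pol$rider[i]
  if (!is.na(rid)) {
    imprint <- rid
    world$fac$busy[rid] <- 2L
    world$fac$x[rid] <- 0; world$fac$y[rid] <- 0; world$fac$z[rid] <- 0
    world <- .log_ev(world, "imprint_transfer", mid, world$fac$id[rid])
    world$pol$rider[i] <- NA_integer_
  }
  world$pol$cls[i] <- "A0"; world$pol$immune[i] <- FALSE
  world$mrna <- rbind(world$mrna, data.frame(
    id = mid, x = 0, y = 0, z = 0, compartment = "nucleus",
    birth = world$tick, engaged_by = NA_integer_, progress = 0L,
    imprint = imprint, alive = TRUE, stringsAsFactors = FALSE))
  world <- .log_ev(world, "mrna_birth", mid, i)
  world
}

#' @rdname step_world
#' @export
mrna_lifecycle <- function(world, config) {
  Rn <- config$nucleus_radius
  for (m in seq_len(nrow(world$mrna))) {
    if (!world$mrna$alive[m]) next
    if (world$mrna$compartment[m] == "cytoplasm" &&
        is.na(world$mrna$engaged_by[m])) {
      imp <- world$mrna$imprint[m]
      if (!is.na(imp)) {               # imprinted mRNA: immediate engagement
        world$mrna$engaged_by[m] <- imp
        world$fac$busy[imp] <- 3L
        world <- .log_ev(world, "decay_engage", m, world$fac$id[imp])
      } else {
        mp <- c(world$mrna$x[m], world$mrna$y[m], world$mrna$z[m])
        cand <- which(world$fac$type %in% c("ccr4", "xrn1") &
                        world$fac$busy == 0L)
        if (length(cand)) {
          fr <- sqrt(world$fac$x[cand]^2 + world$fac$y[cand]^2 +
                       world$fac$z[cand]^2)
          cand <- cand[fr > Rn]        # decay happens in the cytoplasm
        }
        if (length(cand)) {
          dd <- sqrt((world$fac$x[cand] - mp[1])^2 +
                       (world$fac$y[cand] - mp[2])^2 +
                       (world$fac$z[cand] - mp[3])^2)
          ok <- dd <= config$radius_decay
          if (any(ok)) {
            j <- cand[ok][which.min(dd[ok])]
            world$mrna$engaged_by[m] <- j
            world$fac$busy[j] <- 3L
            world$fac$x[j] <- mp[1]; world$fac$y[j] <- mp[2]; world$fac$z[j] <- mp[3]
            world <- .log_ev(world, "decay_engage", m, world$fac$id[j])
          }
        }
      }
    }
    eb <- world$mrna$engaged_by[m]
    if (!is.na(eb)) {
      world$mrna$progress[m] <- world$mrna$progress[m] + 1L
      if (world$mrna$progress[m] >= config$degradation_ticks) {
        world <- .log_ev(world, "degradation_complete", m, world$fac$id[eb])
        world$fac$busy[eb] <- 0L
        world$mrna$engaged_by[m] <- NA_integer_
        world$mrna$imprint[m] <- NA_integer_
        world$mrna$alive[m] <- FALSE
        world <- .log_ev(world, "mrna_death", m)
      }
    } else if (config$mrna_basal_decay > 0 &&
               runif(1) < config$mrna_basal_decay) {
      imp <- world$mrna$imprint[m]
      if (!is.na(imp)) world$fac$busy[imp] <- 0L
      world$mrna$imprint[m] <- NA_integer_
      world$mrna$alive[m] <- FALSE
      world <- .log_ev(world, "basal_decay", m)
      world <- .log_ev(world, "mrna_death", m)
    }
  }
  world
}

.movement_phase <- function(world, config) {
  geom <- list(nucleus_radius = config$nucleus_radius,
               cytoplasm_radius = config$cytoplasm_radius)
  for (i in which(world$pol$phase == "free")) {
    p <- move_agent(.pol_pos(world, i), config$step_polymerase, "nucleus", geom)
    world$pol$x[i] <- p[1]; world$pol$y[i] <- p[2]; world$pol$z[i] <- p[3]
  }
  for (i in which(world$fac$busy == 0L)) {
    type <- world$fac$type[i]
    s <- switch(type, tfiis = config$step_tfiis, ccr4 = config$step_ccr4,
                xrn1 = config$step_xrn1)
    conf <- if (type == "tfiis") "nucleus" else "cell"
    p <- move_agent(.fac_pos(world, i), s, conf, geom)
    world$fac$x[i] <- p[1]; world$fac$y[i] <- p[2]; world$fac$z[i] <- p[3]
  }
  for (m in which(world$mrna$alive & is.na(world$mrna$engaged_by))) {
    p0 <- c(world$mrna$x[m], world$mrna$y[m], world$mrna$z[m])
    if (world$mrna$compartment[m] == "nucleus") {
      p <- p0 + .rand_step(config$step_mrna)
      if (sqrt(sum(p^2)) > config$nucleus_radius) {   # export on crossing
        world$mrna$compartment[m] <- "cytoplasm"
        p <- .reflect_outer(p, config$cytoplasm_radius)
        world <- .log_ev(world, "export", m)
      }
    } else {
      p <- move_agent(p0, config$step_mrna, "cytoplasm", geom)
    }
    world$mrna$x[m] <- p[1]; world$mrna$y[m] <- p[2]; world$mrna$z[m] <- p[3]
    imp <- world$mrna$imprint[m]
    if (!is.na(imp)) {
      world$fac$x[imp] <- p[1]; world$fac$y[imp] <- p[2]; world$fac$z[imp] <- p[3]
    }
  }
  world
}
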
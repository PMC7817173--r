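## Stochastic clone growth on a hexagonal basal-layer lattice.
##
## Executable form of the renewing-edge / differentiating-core model: each
## basal cell divides at rate lambda; the division type (SR/AD/SD) is
## drawn from a fate-probability triplet chosen by the cell's local
## context.  A mutant cell whose neighborhood is sufficiently homotypic
## (all-mutant by default) uses the "inner" triplet, otherwise the
## "edge" triplet; wild-type cells use the distant or clone-adjacent
## triplet.  SR places the second daughter in an adjacent free lattice
## site (shortest-path displacement of neighbors if the neighborhood is
## full); AD delaminates one daughter; SD delaminates both.

.sim_contexts <- c("wt_distant", "wt_adjacent", "hras_edge", "hras_inner")
.sim_context_schema <- c(wt_distant = "wt_distant", wt_adjacent = "wt_adjacent",
                         hras_edge = "clone_edge", hras_inner = "clone_inner")

#' Context-dependent fate-probability triplets
#'
#' Default triplets: wild-type distant cells use the measured control
#' fractions (0.29, 0.44, 0.27), renewal 0.505; clone-adjacent wild-type
#' cells (0.19, 0.44, 0.37), renewal 0.41; mutant edge/single cells the
#' measured oncogenic fractions (0.48, 0.42, 0.10), renewal 0.69; mutant
#' inner cells (0.24, 0.42, 0.34), renewal 0.45 (below the homeostatic
#' 0.5, so the clone core loses progenitors).
#'
#' @param wt_distant,wt_adjacent,hras_edge,hras_inner Numeric triplets
#'   `(p_SR, p_AD, p_SD)`, each summing to 1.
#' @return A 4 x 3 matrix of class `fate_params` (rows: contexts).
#' @export
fate_params <- function(wt_distant = c(0.29, 0.44, 0.27),
                        wt_adjacent = c(0.19, 0.44, 0.37),
                        hras_edge = c(0.48, 0.42, 0.10),
                        hras_inner = c(0.24, 0.42, 0.34)) {
  m <- rbind(wt_distant, wt_adjacent, hras_edge, hras_inner)
  colnames(m) <- c("p_SR", "p_AD", "p_SD")
  rownames(m) <- .sim_contexts
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-8))
    stop("each fate triplet must be non-negative and sum to 1",
         call. = FALSE)
  structure(m, class = c("fate_params", "matrix"))
}

#' Renewal rate implied by a fate triplet
#' @param triplet Numeric `(p_SR, p_AD, p_SD)`.
#' @return `p_SR + p_AD / 2`.
#' @export
triplet_renewal <- function(triplet) triplet[1] + triplet[2] / 2

#' Simulation configuration
#'
#' @param grid_radius Hexagonal grid radius in cells (sites with hex
#'   distance above this from the origin are outside the simulated patch).
#' @param division_rate_per_day Per-cell division rate lambda (1/day).
#'   The default, 0.3/day, corresponds to roughly two divisions per cell
#'   per week, a typical adult interfollicular turnover; it is a
#'   calibrated free parameter, not a measured one.
#' @param homotypic_threshold A mutant cell whose fraction of occupied
#'   mutant neighbor sites (out of 6) is at least this value uses the
#'   inner triplet.  The default 5/6 is the lattice form of "surrounded
#'   by clone cells": on smooth clone geometry it classifies exactly as a
#'   strict all-neighbors rule (boundary cells always have at least two
#'   exposed sites), but it is robust to single-site boundary
#'   fluctuations, which under a strict rule flip interior cells into the
#'   pro-renewal edge state and feed an interface roughening instability.
#' @param duration_days,dt_days Total simulated time and time step.  The
#'   step uses first-order Bernoulli event sampling, so
#'   `dt_days * division_rate_per_day` must not exceed 0.1.
#' @param seed Mandatory RNG seed.
#' @param fate_params A [fate_params()] matrix.
#' @param neighborhood_mode `"context_rule"` (triplet chosen from the live
#'   neighborhood) or `"fixed_probabilities"` (every clone cell uses
#'   `fixed_context`'s triplet; well-mixed branching-process behavior).
#' @param fixed_context Context row used in `fixed_probabilities` mode.
#' @param init `"single"` (one founder cell) or `"disc"` (hexagonal disc
#'   of radius `init_radius`).
#' @param init_radius Founder disc radius for `init = "disc"`.
#' @param genotype Founder genotype, `"HrasG12V"` or `"WT"`.
#' @param wt_background Surround the founder with a confluent sheet of
#'   wild-type cells out to `background_radius`; displacement then pushes
#'   or pulls radial chains of cells through the sheet.  Off by default:
#'   the isolated-clone mode treats empty lattice sites as the
#'   surrounding (unsimulated) wild-type tissue, which avoids the
#'   interface mixing that chain displacement causes in a passive sheet.
#'   Background cells divide only if `background_divides`.
#' @param background_radius,background_divides See `wt_background`.
#' @param wt_adjacent_rule Apply the reduced-renewal triplet to wild-type
#'   cells touching a mutant (on by default); when off they use the
#'   distant triplet regardless.
#' @param gap_closure Close interior vacancies left by symmetric
#'   differentiation (on by default): in a confluent epithelium an
#'   extrusion gap is resealed by neighbor rearrangement, so the vacancy
#'   is chain-shifted to the nearest clone boundary instead of persisting
#'   as a hole that would spuriously expose core cells.
#' @param cell_spacing_um Center-to-center lattice spacing in microns.
#' @param record_interval_days Trajectory sampling interval.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(grid_radius = 40,
                       division_rate_per_day = 0.3,
                       homotypic_threshold = 5 / 6,
                       duration_days = 112,
                       dt_days = 0.05,
                       seed,
                       fate_params = clonedyn::fate_params(),
                       neighborhood_mode = c("context_rule",
                                             "fixed_probabilities"),
                       fixed_context = "hras_edge",
                       init = c("single", "disc"),
                       init_radius = 1,
                       genotype = c("HrasG12V", "WT"),
                       wt_background = FALSE,
                       background_radius = grid_radius - 5,
                       background_divides = FALSE,
                       wt_adjacent_rule = TRUE,
                       gap_closure = TRUE,
                       cell_spacing_um = 10,
                       record_interval_days = 7) {
  if (missing(seed)) stop("sim_config requires an explicit seed",
                          call. = FALSE)
  neighborhood_mode <- match.arg(neighborhood_mode)
  init <- match.arg(init)
  genotype <- match.arg(genotype)
  fixed_context <- match.arg(fixed_context, .sim_contexts)
  stopifnot(grid_radius >= 2, division_rate_per_day >= 0, dt_days > 0,
            duration_days > 0, homotypic_threshold >= 0,
            homotypic_threshold <= 1, cell_spacing_um > 0)
  if (dt_days * division_rate_per_day > 0.1)
    stop("dt_days * division_rate_per_day must be <= 0.1 ",
         "(first-order event sampling)", call. = FALSE)
  if (!inherits(fate_params, "fate_params"))
    stop("fate_params must be built with fate_params()", call. = FALSE)
  structure(list(
    grid_radius = as.integer(grid_radius),
    division_rate_per_day = division_rate_per_day,
    homotypic_threshold = homotypic_threshold,
    duration_days = duration_days, dt_days = dt_days,
    seed = as.integer(seed), fate_params = fate_params,
    neighborhood_mode = neighborhood_mode, fixed_context = fixed_context,
    init = init, init_radius = as.integer(init_radius), genotype = genotype,
    wt_background = wt_background,
    background_radius = as.integer(background_radius),
    background_divides = background_divides,
    wt_adjacent_rule = wt_adjacent_rule,
    gap_closure = gap_closure,
    cell_spacing_um = cell_spacing_um,
    record_interval_days = record_interval_days), class = "sim_config")
}

## axial hex neighbor offsets
.hexq <- c(1L, -1L, 0L, 0L, 1L, -1L)
.hexr <- c(0L, 0L, 1L, -1L, -1L, 1L)

.hex_dist0 <- function(q, r) (abs(q) + abs(r) + abs(q + r)) / 2

#' Axial coordinates of a hexagonal disc
#'
#' @param radius Hex radius (0 = single site).
#' @param spacing Center-to-center spacing in microns.
#' @return Data frame `q`, `r`, `x_um`, `y_um`.
#' @export
hex_disc <- function(radius, spacing = 10) {
  stopifnot(radius >= 0)
  g <- expand.grid(q = -radius:radius, r = -radius:radius)
  g <- g[.hex_dist0(g$q, g$r) <= radius, , drop = FALSE]
  g$x_um <- spacing * (g$q + g$r / 2)
  g$y_um <- spacing * sqrt(3) / 2 * g$r
  rownames(g) <- NULL
  g
}

#' Synthetic compact clone on a hexagonal lattice
#'
#' Builds a cell table for a hexagonal disc clone (7 cells at radius 1,
#' 19 at radius 2, ...), optionally surrounded by rings of wild-type
#' neighbor cells.
#'
#' @param radius Clone hex radius.
#' @param spacing Lattice spacing in microns.
#' @param clone_id,animal_id Identifiers used in the table.
#' @param genotype Clone genotype label.
#' @param wt_ring Number of additional wild-type rings around the clone.
#' @return A standard cell table (see [read_cell_table()]).
#' @examples
#' rosette <- hex_disc_clone(1)        # 7-cell rosette
#' nrow(rosette)
#' @export
hex_disc_clone <- function(radius, spacing = 10, clone_id = "clone1",
                           animal_id = "sim1", genotype = "HrasG12V",
                           wt_ring = 0) {
  g <- hex_disc(radius + wt_ring, spacing)
  inner <- .hex_dist0(g$q, g$r) <= radius
  data.frame(
    animal_id = animal_id,
    clone_id = ifelse(inner, clone_id, NA_character_),
    cell_id = sprintf("c%03d", seq_len(nrow(g))),
    x_um = g$x_um, y_um = g$y_um, layer = "basal",
    genotype = ifelse(inner, genotype, "WT"),
    edu = 0L, brdu = 0L, k10 = 0L, stringsAsFactors = FALSE)
}

#' Expected population size of a well-mixed progenitor pool
#'
#' Branching-process expectation `N0 * exp(lambda * (2 r - 1) * t)`: at
#' renewal rate r = 0.5 the pool is stable, above it grows exponentially.
#'
#' @param N0 Initial basal-cell count.
#' @param lambda Division rate (1/day).
#' @param r Renewal rate in \[0, 1\].
#' @param t Time in days.
#' @return Expected basal-cell count.
#' @export
expected_growth <- function(N0, lambda, r, t) {
  stopifnot(r >= 0, r <= 1, lambda >= 0)
  N0 * exp(lambda * (2 * r - 1) * t)
}

#' Run a lattice clone-growth simulation
#'
#' Simulates a single clone under a [sim_config()] and returns its
#' trajectory together with output tables in the standard schemas, so the
#' result feeds directly into [estimate_fate_fractions()],
#' [clone_morphometrics()] and friends.
#'
#' @param config A [sim_config()].
#' @return List of class `clone_sim`: `trajectory` (per-interval counts,
#'   edge fraction, morphometrics and realized fate fractions), `cells`
#'   (final cell table; delaminated cells appear with
#'   `layer = "suprabasal"`, `k10 = 1`), `events` (division-event table),
#'   `n_basal_final`, `n_delaminations`, `extinct`, `config`.
#' @examples
#' sim <- run_clone_sim(sim_config(seed = 1, duration_days = 28))
#' sim$trajectory[, c("time_days", "n_basal", "edge_fraction")]
#' @export
run_clone_sim <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$grid_radius
  off <- G + 2L                         # matrix padding offset
  side <- 2L * G + 3L
  occ <- matrix(0L, side, side)
  ## mark sites outside the hexagonal patch as invalid
  qq <- rep(seq_len(side) - off, times = side)
  rr <- rep(seq_len(side) - off, each = side)
  occ[.hex_dist0(qq, rr) > G] <- -1L

  cap <- 1024L
  e <- new.env(parent = emptyenv())
  e$q <- integer(cap); e$r <- integer(cap)
  e$gen <- integer(cap); e$clone <- integer(cap)
  e$ctx <- integer(cap)                 # fixed-mode context code
  e$alive <- logical(cap)
  e$ncell <- 0L
  e$occ <- occ
  e$vis <- matrix(0L, side, side)
  e$stamp <- 0L

  grow <- function(n_extra) {
    while (e$ncell + n_extra > length(e$q)) {
      k <- length(e$q)
      e$q <- c(e$q, integer(k)); e$r <- c(e$r, integer(k))
      e$gen <- c(e$gen, integer(k)); e$clone <- c(e$clone, integer(k))
      e$ctx <- c(e$ctx, integer(k)); e$alive <- c(e$alive, logical(k))
    }
  }
  add_cell <- function(q, r, gen, clone, ctx) {
    grow(1L)
    i <- e$ncell + 1L
    e$ncell <- i
    e$q[i] <- q; e$r[i] <- r; e$gen[i] <- gen; e$clone[i] <- clone
    e$ctx[i] <- ctx; e$alive[i] <- TRUE
    e$occ[q + off, r + off] <- i
    i
  }

  gen0 <- if (config$genotype == "HrasG12V") 2L else 1L
  ctx0 <- match(config$fixed_context, .sim_contexts)
  founder <- if (config$init == "single") hex_disc(0) else
    hex_disc(config$init_radius)
  for (i in seq_len(nrow(founder)))
    add_cell(founder$q[i], founder$r[i], gen0, 1L, ctx0)
  if (config$wt_background) {
    bg <- hex_disc(config$background_radius)
    bg <- bg[.hex_dist0(bg$q, bg$r) >
               (if (config$init == "single") 0 else config$init_radius), ,
             drop = FALSE]
    for (i in seq_len(nrow(bg)))
      add_cell(bg$q[i], bg$r[i], 1L, 0L, 1L)
  }

  ## division-event log
  ev_cap <- 4096L
  ev_time <- numeric(ev_cap); ev_ctx <- integer(ev_cap)
  ev_fate <- integer(ev_cap); ev_clone <- integer(ev_cap)
  ev_n <- 0L
  log_event <- function(time, ctx, fate, clone) {
    if (ev_n + 1L > length(ev_time)) {
      k <- length(ev_time)
      ev_time <<- c(ev_time, numeric(k)); ev_ctx <<- c(ev_ctx, integer(k))
      ev_fate <<- c(ev_fate, integer(k)); ev_clone <<- c(ev_clone, integer(k))
    }
    ev_n <<- ev_n + 1L
    ev_time[ev_n] <<- time; ev_ctx[ev_n] <<- ctx
    ev_fate[ev_n] <<- fate; ev_clone[ev_n] <<- clone
  }

  ## delaminated (suprabasal) cell log
  sb_q <- integer(ev_cap); sb_r <- integer(ev_cap); sb_gen <- integer(ev_cap)
  sb_clone <- integer(ev_cap); sb_time <- numeric(ev_cap)
  sb_n <- 0L
  log_sb <- function(q, r, gen, clone, time) {
    if (sb_n + 1L > length(sb_q)) {
      k <- length(sb_q)
      sb_q <<- c(sb_q, integer(k)); sb_r <<- c(sb_r, integer(k))
      sb_gen <<- c(sb_gen, integer(k)); sb_clone <<- c(sb_clone, integer(k))
      sb_time <<- c(sb_time, numeric(k))
    }
    sb_n <<- sb_n + 1L
    sb_q[sb_n] <<- q; sb_r[sb_n] <<- r; sb_gen[sb_n] <<- gen
    sb_clone[sb_n] <<- clone; sb_time[sb_n] <<- time
  }

  pm <- unclass(config$fate_params)
  thr <- config$homotypic_threshold
  ctx_rule <- config$neighborhood_mode == "context_rule"
  adj_rule <- config$wt_adjacent_rule
  p_div <- config$division_rate_per_day * config$dt_days
  n_steps <- ceiling(config$duration_days / config$dt_days)

  ## shortest-path displacement: BFS through occupied sites to the nearest
  ## free site, then shift the chain outward by one; returns the freed
  ## (iq, ir) adjacent to the start, or halts on lattice overflow
  displace <- function(iq0, ir0) {
    e$stamp <- e$stamp + 1L
    st <- e$stamp
    qi <- integer(64L); qj <- integer(64L); par <- integer(64L)
    qi[1] <- iq0; qj[1] <- ir0; par[1] <- 0L
    e$vis[iq0, ir0] <- st
    head <- 1L; tail <- 1L; found <- 0L
    while (head <= tail && !found) {
      ci <- qi[head]; cj <- qj[head]
      for (k in 1:6) {
        ni <- ci + .hexq[k]; nj <- cj + .hexr[k]
        o <- e$occ[ni, nj]
        if (o == -1L || e$vis[ni, nj] == st) next
        e$vis[ni, nj] <- st
        tail <- tail + 1L
        qi[tail] <- ni; qj[tail] <- nj; par[tail] <- head
        if (o == 0L) { found <- tail; break }
      }
      head <- head + 1L
    }
    if (!found)
      stop(structure(class = c("clonedyn_boundary_error", "error",
                               "condition"),
                     list(message = "clone reached the lattice boundary",
                          call = NULL)))
    ## walk back from the free site, shifting occupants outward
    p <- found
    while (par[p] != 1L) {
      pp <- par[p]
      mover <- e$occ[qi[pp], qj[pp]]
      e$occ[qi[p], qj[p]] <- mover
      e$q[mover] <- qi[p] - off; e$r[mover] <- qj[p] - off
      e$occ[qi[pp], qj[pp]] <- 0L
      p <- pp
    }
    c(qi[p], qj[p])
  }

  ## gap closure: an interior vacancy (all six neighbors occupied) is
  ## chain-shifted to the nearest exposed cell, emulating resealing of an
  ## extrusion gap in a confluent sheet; cell count is conserved
  bubble_out <- function(iq0, ir0, outside = NULL) {
    e$stamp <- e$stamp + 1L
    st <- e$stamp
    qi <- integer(64L); qj <- integer(64L); par <- integer(64L)
    qi[1] <- iq0; qj[1] <- ir0; par[1] <- 0L
    e$vis[iq0, ir0] <- st
    head <- 1L; tail <- 1L; found <- 0L
    while (head <= tail && !found) {
      ci <- qi[head]; cj <- qj[head]
      for (k in 1:6) {
        ni <- ci + .hexq[k]; nj <- cj + .hexr[k]
        o <- e$occ[ni, nj]
        if (o == -1L || e$vis[ni, nj] == st) next
        if (o == 0L) {                 # head touches open space: head is
          if (is.null(outside) || outside[ni, nj]) {
            found <- head; break       # the exposed end of the chain
          }
          next                         # another enclosed vacancy: ignore
        }
        e$vis[ni, nj] <- st
        tail <- tail + 1L
        qi[tail] <- ni; qj[tail] <- nj; par[tail] <- head
      }
      head <- head + 1L
    }
    if (!found || found == 1L) return(invisible())
    ## shift occupants one step toward the vacancy along the path
    ## (vacancy = path[1], exposed cell = path[end]; its site is freed)
    path <- integer(0)
    p <- found
    while (p != 0L) {
      path <- c(p, path)
      p <- par[p]
    }
    for (k in 2:length(path)) {
      mover <- e$occ[qi[path[k]], qj[path[k]]]
      e$occ[qi[path[k - 1L]], qj[path[k - 1L]]] <- mover
      e$q[mover] <- qi[path[k - 1L]] - off
      e$r[mover] <- qj[path[k - 1L]] - off
      e$occ[qi[path[k]], qj[path[k]]] <- 0L
    }
    invisible()
  }

  ## periodic confluence sweep: vacancies no longer connected to the open
  ## region around the clone (sealed cavities, formed when a boundary
  ## inlet is pinched off) are expelled to the boundary
  shift_mat <- function(m, dq, dr) {
    out <- matrix(FALSE, side, side)
    ri <- seq_len(side - abs(dq)); ci <- seq_len(side - abs(dr))
    out[ri + max(dq, 0L), ci + max(dr, 0L)] <-
      m[ri + max(-dq, 0L), ci + max(-dr, 0L)]
    out
  }
  ring <- matrix(.hex_dist0(qq, rr) == G, side, side)  # outer seed sites
  outside_prev <- NULL
  sweep_cavities <- function() {
    empty <- e$occ == 0L
    outside <- empty & ring
    if (!is.null(outside_prev)) outside <- outside | (outside_prev & empty)
    repeat {
      grown <- outside
      for (k in 1:6)
        grown <- grown | shift_mat(outside, .hexq[k], .hexr[k])
      grown <- grown & empty
      if (identical(grown, outside)) break
      outside <- grown
    }
    cav <- which(empty & !outside)
    for (s in cav) {
      iq <- (s - 1L) %% side + 1L
      ir <- (s - 1L) %/% side + 1L
      bubble_out(iq, ir, outside = outside)
    }
    outside_prev <<- outside
    invisible()
  }

  ## surface relaxation: collapse boundary pockets (empty sites with >= 4
  ## occupied neighbors) by moving in their most-exposed flank cell --
  ## discrete surface diffusion that keeps the clone compact, as
  ## junctional tension does in a real epithelial sheet
  site_xy <- function(iq, ir) {
    q0 <- iq - off; r0 <- ir - off
    c(q0 + r0 / 2, sqrt(3) / 2 * r0)
  }
  relax_surface <- function() {
    for (pass in 1:5) {
      alive_now <- which(e$alive[seq_len(e$ncell)])
      if (!length(alive_now)) break
      cx <- mean(e$q[alive_now] + e$r[alive_now] / 2)
      cy <- mean(sqrt(3) / 2 * e$r[alive_now])
      d2c <- function(iq, ir) {
        p <- site_xy(iq, ir)
        (p[1] - cx)^2 + (p[2] - cy)^2
      }
      empty <- e$occ == 0L
      noccm <- matrix(0L, side, side)
      for (k in 1:6)
        noccm <- noccm + shift_mat(e$occ > 0L, .hexq[k], .hexr[k])
      dents <- which(empty & noccm >= 3L)
      if (!length(dents)) break
      if (length(dents) > 1L) dents <- sample(dents)
      moved <- FALSE
      for (s in dents) {
        iq <- (s - 1L) %% side + 1L
        ir <- (s - 1L) %/% side + 1L
        if (e$occ[iq, ir] != 0L) next
        occv <- e$occ[cbind(iq + .hexq, ir + .hexr)]
        occn <- which(occv > 0L)
        if (length(occn) < 3L) next
        ## fill the concavity from a strictly farther-out flank cell with
        ## its own free exposure: each move lowers the clone's second
        ## moment, a discrete surface-tension flow toward a round shape
        dd <- d2c(iq, ir)
        ok <- occn[vapply(occn, function(k) {
          ex <- sum(e$occ[cbind(iq + .hexq[k] + .hexq,
                                ir + .hexr[k] + .hexr)] == 0L)
          ex >= 2L && d2c(iq + .hexq[k], ir + .hexr[k]) > dd + 1e-9
        }, logical(1))]
        if (!length(ok)) next
        dist_ok <- vapply(ok, function(k)
          d2c(iq + .hexq[k], ir + .hexr[k]), numeric(1))
        best <- ok[dist_ok == max(dist_ok)]
        k <- if (length(best) == 1L) best else
          best[sample.int(length(best), 1L)]
        mover <- occv[k]
        e$occ[iq, ir] <- mover
        e$occ[iq + .hexq[k], ir + .hexr[k]] <- 0L
        e$q[mover] <- iq - off; e$r[mover] <- ir - off
        moved <- TRUE
      }
      if (!moved) break
    }
    ## peninsula retraction: cells holding on by one or two contacts move
    ## to the adjacent site with the most contacts (discrete curvature
    ## flow; only strictly support-increasing moves are made)
    for (pass in 1:5) {
      idx <- which(e$alive[seq_len(e$ncell)])
      if (!length(idx)) break
      cx <- mean(e$q[idx] + e$r[idx] / 2)
      cy <- mean(sqrt(3) / 2 * e$r[idx])
      d2c <- function(iq, ir) {
        p <- site_xy(iq, ir)
        (p[1] - cx)^2 + (p[2] - cy)^2
      }
      moved <- FALSE
      for (ci in idx) {
        iq <- e$q[ci] + off; ir <- e$r[ci] + off
        occv <- e$occ[cbind(iq + .hexq, ir + .hexr)]
        supp <- sum(occv > 0L)
        if (supp > 2L || supp == 0L) next
        d0 <- d2c(iq, ir)
        free <- which(occv == 0L)
        gain <- vapply(free, function(k) {
          sum(e$occ[cbind(iq + .hexq[k] + .hexq,
                          ir + .hexr[k] + .hexr)] > 0L) - 1L
        }, integer(1))   # minus one: its own current site empties
        inward <- vapply(free, function(k)
          d2c(iq + .hexq[k], ir + .hexr[k]) < d0 - 1e-9, logical(1))
        free <- free[inward & gain > supp]
        gain <- gain[inward & gain > supp]
        if (!length(free)) next
        best <- free[gain == max(gain)]
        k <- if (length(best) == 1L) best else
          best[sample.int(length(best), 1L)]
        e$occ[iq, ir] <- 0L
        e$occ[iq + .hexq[k], ir + .hexr[k]] <- ci
        e$q[ci] <- iq + .hexq[k] - off; e$r[ci] <- ir + .hexr[k] - off
        moved <- TRUE
      }
      if (!moved) break
    }
    invisible()
  }

  ## radial hex direction: sample between the two lattice directions
  ## bracketing the site's polar angle, weighted by angular proximity, so
  ## expected displacement is isotropic (a deterministic pick would grow
  ## spikes along the six lattice axes)
  dir_by_angle <- c(1L, 3L, 6L, 2L, 4L, 5L)   # hex dirs at 0,60,...,300 deg
  ray_dir <- function(q0, r0) {
    if (q0 == 0L && r0 == 0L) return(sample.int(6L, 1L))
    x <- q0 + r0 / 2; y <- sqrt(3) / 2 * r0
    sector <- (atan2(y, x) %% (2 * pi)) / (pi / 3)
    k0 <- floor(sector)
    pick <- (k0 + (stats::runif(1) < sector - k0)) %% 6
    dir_by_angle[pick + 1L]
  }

  ## confluent-sheet displacement: push the chain of cells outward along a
  ## radial ray until the first free site; returns the freed adjacent site
  push_ray <- function(iq, ir, k) {
    di <- .hexq[k]; dj <- .hexr[k]
    ci <- iq + di; cj <- ir + dj
    chain_i <- integer(0); chain_j <- integer(0)
    repeat {
      o <- e$occ[ci, cj]
      if (o == -1L) {
        ## open field boundary: a background cell pushed past the edge
        ## leaves the field; a clone cell doing so is a genuine overflow
        last <- if (length(chain_i))
          e$occ[chain_i[length(chain_i)], chain_j[length(chain_j)]] else 0L
        if (last > 0L && e$clone[last] == 0L) {
          e$alive[last] <- FALSE
          e$occ[chain_i[length(chain_i)], chain_j[length(chain_j)]] <- 0L
          chain_i <- chain_i[-length(chain_i)]
          chain_j <- chain_j[-length(chain_j)]
          ci <- ci - di; cj <- cj - dj
          break
        }
        stop(structure(class = c("clonedyn_boundary_error", "error",
                                 "condition"),
                       list(message = sprintf(
                         "clone reached the lattice boundary (t=%.2f, from (%d,%d), dir %d, chain %d, last %d)",
                         e$time, iq - off, ir - off, k, length(chain_i), last),
                            call = NULL)))
      }
      if (o == 0L) break
      chain_i <- c(chain_i, ci); chain_j <- c(chain_j, cj)
      ci <- ci + di; cj <- cj + dj
    }
    for (t in rev(seq_along(chain_i))) {
      mover <- e$occ[chain_i[t], chain_j[t]]
      e$occ[chain_i[t] + di, chain_j[t] + dj] <- mover
      e$q[mover] <- chain_i[t] + di - off
      e$r[mover] <- chain_j[t] + dj - off
      e$occ[chain_i[t], chain_j[t]] <- 0L
    }
    c(iq + di, ir + dj)
  }

  ## confluent-sheet gap resealing: pull the chain of cells inward along a
  ## radial ray so the vacancy left by an extrusion moves to open space
  pull_ray <- function(iq, ir, k) {
    di <- .hexq[k]; dj <- .hexr[k]
    ci <- iq + di; cj <- ir + dj
    prev_i <- iq; prev_j <- ir
    repeat {
      o <- e$occ[ci, cj]
      if (o == -1L || o == 0L) break
      e$occ[prev_i, prev_j] <- o
      e$q[o] <- prev_i - off; e$r[o] <- prev_j - off
      e$occ[ci, cj] <- 0L
      prev_i <- ci; prev_j <- cj
      ci <- ci + di; cj <- cj + dj
    }
    invisible()
  }

  divide <- function(ci) {
    q0 <- e$q[ci]; r0 <- e$r[ci]
    iq <- q0 + off; ir <- r0 + off
    occv <- e$occ[cbind(iq + .hexq, ir + .hexr)]
    nb <- occv[occv > 0L]
    n_mut <- if (length(nb)) sum(e$gen[nb] == 2L) else 0L
    if (ctx_rule) {
      ctx <- if (e$gen[ci] == 2L) {
        if (n_mut / 6 >= thr) 4L else 3L
      } else {
        if (adj_rule && n_mut > 0L) 2L else 1L
      }
    } else {
      ctx <- e$ctx[ci]
    }
    u <- stats::runif(1)
    fate <- if (u < pm[ctx, 1]) 1L else if (u < pm[ctx, 1] + pm[ctx, 2]) 2L
            else 3L
    log_event(e$time, ctx, fate, e$clone[ci])
    if (fate == 1L) {                   # SR: place second basal daughter
      free <- which(occv == 0L)
      if (length(free)) {
        ## adhesion-biased placement: prefer the free site with the most
        ## occupied neighbors (fills concavities, keeps the clone compact)
        if (length(free) > 1L) {
          support <- vapply(free, function(k) {
            sum(e$occ[cbind(iq + .hexq[k] + .hexq,
                            ir + .hexr[k] + .hexr)] > 0L)
          }, integer(1))
          best <- free[support == max(support)]
          k <- if (length(best) == 1L) best else
            best[sample.int(length(best), 1L)]
        } else {
          k <- free
        }
        add_cell(q0 + .hexq[k], r0 + .hexr[k], e$gen[ci], e$clone[ci],
                 e$ctx[ci])
      } else {
        site <- if (config$wt_background)
          push_ray(iq, ir, ray_dir(q0, r0)) else displace(iq, ir)
        add_cell(site[1] - off, site[2] - off, e$gen[ci], e$clone[ci],
                 e$ctx[ci])
      }
    } else if (fate == 2L) {            # AD: one daughter delaminates
      log_sb(q0, r0, e$gen[ci], e$clone[ci], e$time)
    } else {                            # SD: both delaminate, site freed
      log_sb(q0, r0, e$gen[ci], e$clone[ci], e$time)
      log_sb(q0, r0, e$gen[ci], e$clone[ci], e$time)
      e$alive[ci] <- FALSE
      e$occ[iq, ir] <- 0L
      if (config$gap_closure) {
        if (config$wt_background) {
          pull_ray(iq, ir, ray_dir(q0, r0))
        } else {
          occv2 <- e$occ[cbind(iq + .hexq, ir + .hexr)]
          if (!any(occv2 > 0L)) {
            ## isolated vacancy: nothing to rearrange
          } else if (any(occv2 == 0L)) {
            ## boundary dent: refill from the most-exposed flank neighbor
            ## (local rearrangement, smooths the clone surface)
            occn <- which(occv2 > 0L)
            expo <- vapply(occn, function(k) {
              sum(e$occ[cbind(iq + .hexq[k] + .hexq,
                              ir + .hexr[k] + .hexr)] == 0L)
            }, integer(1))
            best <- occn[expo == max(expo)]
            k <- if (length(best) == 1L) best else
              best[sample.int(length(best), 1L)]
            mover <- occv2[k]
            e$occ[iq, ir] <- mover
            e$occ[iq + .hexq[k], ir + .hexr[k]] <- 0L
            e$q[mover] <- iq - off; e$r[mover] <- ir - off
          } else {
            bubble_out(iq, ir)          # enclosed vacancy: expel outward
          }
        }
      }
    }
  }

  ## trajectory recording
  spacing <- config$cell_spacing_um
  traj <- list()
  last_ev <- 0L
  record <- function() {
    idx <- which(e$alive[seq_len(e$ncell)] & e$clone[seq_len(e$ncell)] == 1L)
    n <- length(idx)
    n_edge <- 0L
    if (n) {
      for (ci in idx) {
        occv <- e$occ[cbind(e$q[ci] + off + .hexq, e$r[ci] + off + .hexr)]
        nb <- occv[occv > 0L]
        exposed <- length(nb) < 6L || any(e$clone[nb] != 1L)
        if (exposed) n_edge <- n_edge + 1L
      }
    }
    circ <- NA_real_; dens <- NA_real_
    if (n >= 3L) {
      x <- spacing * (e$q[idx] + e$r[idx] / 2)
      y <- spacing * sqrt(3) / 2 * e$r[idx]
      if (!.is_collinear(x, y)) {
        ell <- fit_ellipse(x, y, input = "points")
        circ <- circularity(ell$area_um2, ell$perimeter_um)
        dens <- n / ell$area_um2
      }
    }
    win <- if (ev_n > last_ev) (last_ev + 1L):ev_n else integer(0)
    nf <- c(sum(ev_fate[win] == 1L), sum(ev_fate[win] == 2L),
            sum(ev_fate[win] == 3L))
    nd <- sum(nf)
    last_ev <<- ev_n
    traj[[length(traj) + 1L]] <<- data.frame(
      time_days = e$time, week = e$time / 7, n_basal = n, n_edge = n_edge,
      n_inner = n - n_edge,
      edge_fraction = if (n) n_edge / n else NA_real_,
      circularity = circ, density_per_um2 = dens,
      n_divisions = nd,
      f_SR = if (nd) nf[1] / nd else NA_real_,
      f_AD = if (nd) nf[2] / nd else NA_real_,
      f_SD = if (nd) nf[3] / nd else NA_real_,
      renewal = if (nd) (nf[1] + nf[2] / 2) / nd else NA_real_)
  }

  e$time <- 0
  record()
  rec_every <- max(1L, round(config$record_interval_days / config$dt_days))
  sweep_every <- max(1L, round(0.25 / config$dt_days))  # every quarter-day
  bg_div <- config$background_divides
  for (s in seq_len(n_steps)) {
    cand <- which(e$alive[seq_len(e$ncell)])
    if (!bg_div && config$wt_background)
      cand <- cand[e$clone[cand] == 1L]
    nc <- length(cand)
    if (nc && p_div > 0) {
      dividers <- cand[stats::runif(nc) < p_div]
      for (ci in dividers) divide(ci)
    }
    e$time <- s * config$dt_days
    if (config$gap_closure && !config$wt_background &&
        s %% sweep_every == 0L) {
      sweep_cavities()
      relax_surface()
    }
    if (s %% rec_every == 0L || s == n_steps) record()
  }

  ## assemble outputs -----------------------------------------------------
  animal <- paste0("sim", config$seed)
  alive_idx <- which(e$alive[seq_len(e$ncell)])
  sbi <- seq_len(sb_n)
  cells <- data.frame(
    animal_id = rep(animal, length(alive_idx) + sb_n),
    clone_id = c(ifelse(e$clone[alive_idx] == 1L, "clone1", NA_character_),
                 ifelse(sb_clone[sbi] == 1L, "clone1", NA_character_)),
    cell_id = c(sprintf("b%05d", alive_idx), sprintf("s%05d", sbi)),
    x_um = spacing * (c(e$q[alive_idx], sb_q[sbi]) +
                        c(e$r[alive_idx], sb_r[sbi]) / 2),
    y_um = spacing * sqrt(3) / 2 * c(e$r[alive_idx], sb_r[sbi]),
    layer = rep(c("basal", "suprabasal"), c(length(alive_idx), sb_n)),
    genotype = ifelse(c(e$gen[alive_idx], sb_gen[sbi]) == 2L, "HrasG12V",
                      "WT"),
    edu = 0L, brdu = 0L,
    k10 = rep(c(0L, 1L), c(length(alive_idx), sb_n)),
    stringsAsFactors = FALSE)

  evi <- seq_len(ev_n)
  fate_lab <- c("SR", "AD", "SD")[ev_fate[evi]]
  events <- data.frame(
    animal_id = rep(animal, ev_n),
    clone_id = ifelse(ev_clone[evi] == 1L, "clone1", NA_character_),
    context = unname(.sim_context_schema[.sim_contexts[ev_ctx[evi]]]),
    week = ev_time[evi] / 7,
    daughter1_layer = ifelse(fate_lab == "SD", "suprabasal", "basal"),
    daughter2_layer = ifelse(fate_lab == "SR", "basal", "suprabasal"),
    daughter1_morph = rep("unknown", ev_n),
    daughter2_morph = rep("unknown", ev_n),
    division_type = fate_lab, time_days = ev_time[evi],
    stringsAsFactors = FALSE)

  n_final <- sum(e$alive[seq_len(e$ncell)] & e$clone[seq_len(e$ncell)] == 1L)
  structure(list(trajectory = do.call(rbind, traj), cells = cells,
                 events = events, n_basal_final = n_final,
                 n_delaminations = sb_n, extinct = n_final == 0L,
                 config = config),
            class = "clone_sim")
}

#' @export
print.clone_sim <- function(x, ...) {
  cat(sprintf(
    "Clone simulation (%s, %g days, seed %d): %d basal cells, %d divisions, %d delaminations%s\n",
    x$config$neighborhood_mode, x$config$duration_days, x$config$seed,
    x$n_basal_final, nrow(x$events), x$n_delaminations,
    if (x$extinct) " [extinct]" else ""))
  invisible(x)
}

#' Context-dependent fate probabilities for a single cell
#'
#' The rule applied at each division of the lattice model, exposed for
#' inspection: a mutant cell whose occupied-mutant neighbor fraction
#' reaches `homotypic_threshold` gets the inner triplet, otherwise the
#' edge triplet; a wild-type cell touching any mutant gets the
#' clone-adjacent triplet, otherwise the distant one.  An isolated cell
#' (no neighbors) uses the edge/distant context.
#'
#' @param genotype `"HrasG12V"` or `"WT"`.
#' @param neighbor_genotypes Character vector of the (up to 6) occupied
#'   neighbor genotypes; empty sites are simply absent.
#' @param params A [fate_params()] matrix.
#' @param homotypic_threshold See [sim_config()].
#' @param mode,fixed_context As in [sim_config()]; in
#'   `fixed_probabilities` mode the `fixed_context` row is returned
#'   unconditionally.
#' @return Named numeric triplet `(p_SR, p_AD, p_SD)` with attribute
#'   `"context"`.
#' @examples
#' fate_probabilities("HrasG12V", rep("HrasG12V", 6))  # inner triplet
#' fate_probabilities("HrasG12V", c("WT", "HrasG12V"))  # edge triplet
#' @export
fate_probabilities <- function(genotype, neighbor_genotypes = character(),
                               params = fate_params(),
                               homotypic_threshold = 1.0,
                               mode = c("context_rule",
                                        "fixed_probabilities"),
                               fixed_context = "hras_edge") {
  mode <- match.arg(mode)
  genotype <- match.arg(genotype, c("HrasG12V", "WT"))
  if (mode == "fixed_probabilities") {
    ctx <- match.arg(fixed_context, .sim_contexts)
  } else {
    n_mut <- sum(neighbor_genotypes == "HrasG12V")
    ctx <- if (genotype == "HrasG12V") {
      if (n_mut / 6 >= homotypic_threshold) "hras_inner" else "hras_edge"
    } else {
      if (n_mut > 0) "wt_adjacent" else "wt_distant"
    }
  }
  out <- unclass(params)[ctx, ]
  attr(out, "context") <- ctx
  out
}
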
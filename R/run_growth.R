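#' Run a growth simulation
#'
#' Grows a tissue from \code{config$init_n} cells until it reaches
#' \code{n_target} cells (or time \code{t_end}). Each event batch advances the
#' cell-cycle clocks, performs due divisions, relaxes the mesh toward
#' mechanical equilibrium, sweeps T1 rearrangements and T2 eliminations,
#' relaxes again, applies any stress feedback, and records the tissue-size
#' series, the event log and periodic snapshots. A run is fully determined by
#' the configuration (including its seed).
#'
#' @param config a \code{\link{sim_config}}.
#' @param n_target stop once the tissue holds this many cells.
#' @param init_tissue optional starting tissue; by default
#'   \code{\link{generate_initial_tissue}} builds one.
#' @param t_end optional time cap (needed when \code{mu = 0}).
#' @param max_batches safety cap on event batches.
#' @param verbose print progress every 100 batches.
#' @return an object of class \code{growth_run}: \code{times}, \code{g}
#'   (cell-count series), \code{events} (data frame: time, kind, ids,
#'   location, trait, area, local stress/density changes), \code{snapshots},
#'   \code{tissue} (final state), \code{stats} (per-batch interior summaries),
#'   \code{trait_counts} (per-batch per-trait cell counts, mixed populations
#'   only), \code{sbar_init}, \code{collapsed} (TRUE when attrition beat
#'   growth and the run stopped early at its last sound state) and
#'   \code{config}.
#' @export
run_growth <- function(config = sim_config(), n_target = 500,
                       init_tissue = NULL, t_end = NULL,
                       max_batches = 200000L, verbose = FALSE) {
  set.seed(config$seed)
  tis <- if (is.null(init_tissue)) {
    generate_initial_tissue(config$init_n, seed = NULL, config = config)
  } else init_tissue
  nc0 <- length(tis$cells)
  if (!is.null(n_target) && n_target <= nc0 && is.null(t_end))
    stop("n_target must exceed the initial cell count")
  st <- tis$state
  hd <- config$heredity
  if (isTRUE(hd$enabled)) {
    N <- length(hd$grid)
    st$trait <- sample.int(N, nc0, replace = TRUE)
    if (hd$param == "lam") st$lam <- hd$grid[st$trait]
    else st$gam <- hd$grid[st$trait]
  }
  if (is.finite(config$cycle_len_mean)) {
    st$cycle_len <- stats::runif(nc0,
      config$cycle_len_mean * (1 - config$cycle_jitter),
      config$cycle_len_mean * (1 + config$cycle_jitter))
    st$clock <- stats::runif(nc0, 0, st$cycle_len)
  } else {
    st$cycle_len <- rep(Inf, nc0)   # mu = 0: nobody ever divides
    st$clock <- rep(0, nc0)
  }
  tis$state <- st
  ## settle to the mechanically equilibrated pre-growth state: the generator
  ## hands over a unit-mean-area tissue, whose equilibrium is denser; cells
  ## extruded while settling are pre-growth losses, not growth events, so the
  ## size bookkeeping starts from the settled count
  settle_elims <- 0L
  for (round in seq_len(40L)) {
    tis <- relax(tis, config, max_steps = 25L, t1_sweeps = TRUE, t1_every = 8L)
    conv <- isTRUE(attr(tis, "converged"))
    tis <- apply_T2(tis, config)
    k2 <- length(attr(tis, "t2_events"))
    settle_elims <- settle_elims + k2
    tis <- resolve_rosettes(tis, config)
    if (conv && k2 == 0L && attr(tis, "n_resolved") == 0L) break
  }
  nc0 <- length(tis$cells)
  fb <- config$feedback
  need_stress <- isTRUE(config$track_stress) || fb$mode != "none"
  smethod <- config$stress_method
  snap_state <- function(tis) {
    a <- cell_areas(tis)
    ch <- cache_of(tis)
    s <- if (need_stress) cell_stress(tis, config, smethod) else NULL
    list(ids = tis$state$id, area = a, boundary = ch$boundary_cell,
         stress = s, adj = cell_adjacency(tis))
  }
  cur <- snap_state(tis)
  ## mean stress magnitude before growth starts (interior cells: the rim's
  ## tripled tension makes boundary cells artificially tensile)
  sbar_init <- if (need_stress) {
    int <- !cur$boundary
    mean(cur$stress$magnitude[if (any(int)) int else TRUE], na.rm = TRUE)
  } else NA_real_
  S0 <- if (!is.null(fb$S0)) fb$S0 else sbar_init
  chi0 <- if (!is.null(fb$chi0)) fb$chi0 else
    if (fb$target == "gam") config$gam0 else config$lam0
  time <- 0
  times <- 0
  gser <- nc0
  ev <- list()
  stats_l <- list()
  traits_l <- list()
  snaps <- list(list(time = 0, tissue = tis))
  next_snap <- nc0 + config$snapshot_every
  ramp <- config$mitosis_mode == "ramp"
  batch <- 0L
  record_stats <- function(cur, time) {
    int <- !cur$boundary
    use <- if (sum(int) >= 3) int else rep(TRUE, length(cur$area))
    a <- cur$area[use]
    list(time = time, n = length(cur$area),
         cv_size = stats::sd(a) / mean(a),
         var_stress = if (need_stress)
           stats::var(cur$stress$magnitude[use], na.rm = TRUE)
         else NA_real_,
         mean_stress = if (need_stress)
           mean(cur$stress$magnitude[use], na.rm = TRUE)
         else NA_real_)
  }
  stats_l[[1]] <- record_stats(cur, 0)
  if (isTRUE(hd$enabled))
    traits_l[[1]] <- tabulate(tis$state$trait, length(hd$grid))
  collapsed <- FALSE
  mit_base <- list()   # neighbourhood stress at each cell's mitosis entry
  repeat {
    batch <- batch + 1L
    if (batch > max_batches) {
      warning("run_growth: max_batches reached before n_target")
      break
    }
    prev_tis <- tis    # last good state if this batch collapses the mesh
    time <- time + config$batch_dt
    prev <- cur
    ok <- tryCatch({
    ## 1. clocks (possibly stress gated) and mitosis
    gate <- 1
    if (fb$mode == "growth_gate") {
      Sc <- prev$stress$magnitude[match(tis$state$id, prev$ids)]
      Sc[is.na(Sc)] <- sbar_init
      gate <- stress_gated_rate(Sc, sbar_init, fb$clock_const)
    }
    tis <- advance_clocks(tis, config$batch_dt, gate, config)
    due <- attr(tis, "divide_now")
    if (ramp) {
      ## cells entering mitosis now: snapshot their neighbourhood stress —
      ## the compression a division exerts builds up over the whole mitotic
      ## expansion, so "before division" is the state at mitosis entry
      entered <- which(tis$state$mitotic & tis$state$mitotic_elapsed == 0)
      if (need_stress && length(entered)) {
        for (ci in entered) {
          id <- tis$state$id[ci]
          at <- match(id, prev$ids)
          if (is.na(at)) next
          nbr_idx <- prev$adj[[at]]
          if (is.null(nbr_idx) || !length(nbr_idx)) next
          mit_base[[as.character(id)]] <- list(
            nbrs = prev$ids[nbr_idx],
            S = mean(prev$stress$magnitude[nbr_idx], na.rm = TRUE))
        }
      }
      tis <- mitotic_growth(tis, config$batch_dt, config)
      due <- attr(tis, "divide_now")
    }
    ## 2. divisions
    for (ci in due) {
      xy <- tis$pos[tis$cells[[ci]], , drop = FALSE]
      angle <- if (fb$mode == "division_align") {
        srow <- prev$stress[match(tis$state$id[ci], prev$ids), ]
        if (is.na(srow$sxx)) sample_division_axis(xy, config$kappa)
        else stress_aligned_axis(matrix(c(srow$sxx, srow$sxy,
                                          srow$sxy, srow$syy), 2, 2), xy)
      } else sample_division_axis(xy, config$kappa)
      pid <- tis$state$id[ci]
      tis <- divide_cell(tis, ci, angle, config)
      e <- attr(tis, "event")
      if (is.null(e)) next
      base <- mit_base[[as.character(pid)]]
      if (!is.null(base)) mit_base[[as.character(pid)]] <- NULL
      nbrs_idx <- prev$adj[[match(pid, prev$ids)]]
      nbr_ids <- if (!is.null(base)) base$nbrs
                 else if (length(nbrs_idx)) prev$ids[nbrs_idx]
                 else integer(0)
      ## "after division" is the state the division leaves behind, measured
      ## before the tissue has relaxed the crowding away
      after_S <- if (need_stress && length(nbr_ids)) {
        sm <- cell_stress(tis, config, smethod)$magnitude
        mean(sm[match(nbr_ids, tis$state$id)], na.rm = TRUE)
      } else NA_real_
      ev[[length(ev) + 1L]] <- list(
        time = time, kind = "division", cell = pid,
        d1 = e$d1, d2 = e$d2, x = e$x, y = e$y,
        trait = if (is.na(e$trait)) NA_integer_ else e$trait,
        area = e$area,
        nbr_ids = nbr_ids,
        base_S = if (!is.null(base)) base$S else NULL,
        after_S = after_S)
    }
    ## 3. relax (T1 sweeps interleaved), then eliminations, then relax again
    log_t1 <- function(evl) {
      for (t1e in evl) {
        ev[[length(ev) + 1L]] <<- list(time = time, kind = "t1",
                                       cell = NA_integer_, d1 = NA_integer_,
                                       d2 = NA_integer_, x = t1e$x, y = t1e$y,
                                       trait = NA_integer_, area = NA_real_,
                                       nbr_ids = integer(0))
      }
    }
    n_t1 <- 0L
    rounds <- max(1L, ceiling(config$relax_max_steps / 15))
    for (round in seq_len(rounds)) {
      tis <- relax(tis, config, max_steps = 15L, t1_sweeps = TRUE,
                   t1_every = 8L)
      n_t1 <- n_t1 + attr(tis, "n_t1")
      log_t1(attr(tis, "t1_events"))
      conv <- isTRUE(attr(tis, "converged"))
      tis <- apply_T1(tis, config)
      n_t1 <- n_t1 + attr(tis, "n_t1")
      log_t1(attr(tis, "t1_events"))
      tis <- apply_T2(tis, config)
      t2e <- attr(tis, "t2_events")
      for (e in t2e) {
        at <- match(e$id, prev$ids)
        nbrs_idx <- if (!is.na(at)) prev$adj[[at]] else NULL
        ev[[length(ev) + 1L]] <- list(
          time = time, kind = "t2", cell = e$id, d1 = NA_integer_,
          d2 = NA_integer_, x = e$x, y = e$y,
          trait = if (is.na(e$trait)) NA_integer_ else e$trait, area = e$area,
          nbr_ids = if (length(nbrs_idx)) prev$ids[nbrs_idx] else integer(0))
      }
      tis <- resolve_rosettes(tis, config)
      if (conv && !length(t2e) && attr(tis, "n_t1") == 0L &&
          attr(tis, "n_resolved") == 0L) break
    }
    ## a cell inverted late in the last round must be extruded before metrics
    guard <- 0L
    while (guard < 3L && min(cell_areas(tis)) <= 0) {
      guard <- guard + 1L
      tis <- relax(tis, config, max_steps = 10L)
      tis <- apply_T2(tis, config)
      for (e in attr(tis, "t2_events")) {
        at <- match(e$id, prev$ids)
        nbrs_idx <- if (!is.na(at)) prev$adj[[at]] else NULL
        ev[[length(ev) + 1L]] <- list(
          time = time, kind = "t2", cell = e$id, d1 = NA_integer_,
          d2 = NA_integer_, x = e$x, y = e$y,
          trait = if (is.na(e$trait)) NA_integer_ else e$trait, area = e$area,
          nbr_ids = if (length(nbrs_idx)) prev$ids[nbrs_idx] else integer(0))
      }
    }
    ## 4. post-batch state, feedback, local event metrics
    cur <- snap_state(tis)
    TRUE
    }, error = function(e) {
      if (grepl("collaps|positive area", conditionMessage(e)))
        FALSE
      else stop(e)
    })
    if (!ok) {    # attrition beat growth: return the last sound state
      collapsed <- TRUE
      tis <- prev_tis
      cur <- prev
      warning("run_growth: tissue collapsed at time ", time,
              "; returning the last sound state")
      break
    }
    if (fb$mode %in% c("fluidity_self", "fluidity_neighbor")) {
      S <- cur$stress$magnitude
      S[!is.finite(S)] <- S0     # inverted transients: no feedback drive
      S_ref <- if (fb$mode == "fluidity_self") rep(S0, length(S)) else
        vapply(seq_along(cur$adj), function(i) {
          nb <- cur$adj[[i]]
          if (length(nb)) mean(S[nb]) else S[i]
        }, 0)
      ## rim cells carry the artificial tripled boundary tension and sit in a
      ## strongly tensile state; driving them destabilises the rim, so the
      ## feedback regulates interior cells and lets rim cells relax to basal
      S[cur$boundary] <- S_ref[cur$boundary]
      chi <- if (fb$target == "gam") tis$state$gam else tis$state$lam
      chi <- fluidity_feedback_step(chi, S, S_ref, fb$c, fb$d, chi0,
                                    config$batch_dt)
      if (fb$target == "gam") tis$state$gam <- chi else tis$state$lam <- chi
    }
    if (length(ev)) {
      ## fill before/after neighbourhood metrics for this batch's events
      last <- length(ev)
      while (last >= 1 && is.null(ev[[last]]$done) &&
             ev[[last]]$time == time) {
        e <- ev[[last]]
        nbr <- e$nbr_ids
        ib <- match(nbr, prev$ids)
        ia <- match(nbr, cur$ids)
        keep <- !is.na(ib) & !is.na(ia)
        if (need_stress && e$kind == "division" &&
            !is.null(e$after_S) && is.finite(e$after_S)) {
          ## before: parent's mitosis entry (or previous batch); after: the
          ## unrelaxed post-division state
          before_S <- if (!is.null(e$base_S)) e$base_S
                      else if (sum(!is.na(ib)) >= 1)
                        mean(prev$stress$magnitude[ib[!is.na(ib)]], na.rm = TRUE)
                      else NA_real_
          e$ds_local <- if (is.finite(before_S)) e$after_S - before_S
                        else NA_real_
        } else if (need_stress && sum(keep) >= 1 &&
                   e$kind %in% c("division", "t2")) {
          e$ds_local <- mean(cur$stress$magnitude[ia[keep]], na.rm = TRUE) -
            mean(prev$stress$magnitude[ib[keep]], na.rm = TRUE)
        } else e$ds_local <- NA_real_
        if (e$kind == "t2" && sum(keep) >= 3) {
          fi <- match(e$cell, prev$ids)
          invb <- 1 / prev$area[c(fi, ib[keep])]
          inva <- 1 / cur$area[ia[keep]]
          e$cv_before <- stats::sd(invb) / mean(invb)
          e$cv_after <- stats::sd(inva) / mean(inva)
        } else {
          e$cv_before <- NA_real_
          e$cv_after <- NA_real_
        }
        e$done <- TRUE
        ev[[last]] <- e
        last <- last - 1L
      }
    }
    nc <- length(tis$cells)
    times <- c(times, time)
    gser <- c(gser, nc)
    stats_l[[length(stats_l) + 1L]] <- record_stats(cur, time)
    if (isTRUE(hd$enabled))
      traits_l[[length(traits_l) + 1L]] <-
        tabulate(tis$state$trait, length(hd$grid))
    if (nc >= next_snap) {
      snaps[[length(snaps) + 1L]] <- list(time = time, tissue = tis)
      next_snap <- next_snap + config$snapshot_every
    }
    if (verbose && batch %% 100L == 0L)
      message(sprintf("t = %.0f, %d cells, %d events", time, nc, length(ev)))
    if (!is.null(n_target) && nc >= n_target) break
    if (!is.null(t_end) && time >= t_end) break
    if (nc < 10) {
      collapsed <- TRUE
      warning("run_growth: tissue collapsed at time ", time)
      break
    }
  }
  snaps[[length(snaps) + 1L]] <- list(time = time, tissue = tis)
  events <- if (length(ev)) {
    data.frame(
      time = vapply(ev, `[[`, 0, "time"),
      kind = vapply(ev, `[[`, "", "kind"),
      cell = vapply(ev, `[[`, 0L, "cell"),
      d1 = vapply(ev, `[[`, 0L, "d1"),
      d2 = vapply(ev, `[[`, 0L, "d2"),
      x = vapply(ev, `[[`, 0, "x"),
      y = vapply(ev, `[[`, 0, "y"),
      trait = vapply(ev, `[[`, 0L, "trait"),
      area = vapply(ev, `[[`, 0, "area"),
      ds_local = vapply(ev, function(e)
        if (is.null(e$ds_local)) NA_real_ else e$ds_local, 0),
      cv_before = vapply(ev, function(e)
        if (is.null(e$cv_before)) NA_real_ else e$cv_before, 0),
      cv_after = vapply(ev, function(e)
        if (is.null(e$cv_after)) NA_real_ else e$cv_after, 0))
  } else {
    data.frame(time = numeric(0), kind = character(0), cell = integer(0),
               d1 = integer(0), d2 = integer(0), x = numeric(0),
               y = numeric(0), trait = integer(0), area = numeric(0),
               ds_local = numeric(0), cv_before = numeric(0),
               cv_after = numeric(0))
  }
  stats <- do.call(rbind, lapply(stats_l, as.data.frame))
  out <- list(times = times, g = gser, events = events, snapshots = snaps,
              tissue = tis, stats = stats,
              trait_counts = if (length(traits_l))
                do.call(rbind, traits_l) else NULL,
              sbar_init = sbar_init, settle_eliminations = settle_elims,
              collapsed = collapsed, config = config)
  class(out) <- "growth_run"
  out
}

#' @export
print.growth_run <- function(x, ...) {
  nd <- sum(x$events$kind == "division")
  ne <- sum(x$events$kind == "t2")
  nt <- sum(x$events$kind == "t1")
  cat(sprintf("growth run: %d -> %d cells over %.0f time units\n",
              x$g[1], x$g[length(x$g)], max(x$times)))
  cat(sprintf("  %d divisions, %d eliminations (overall ratio %.3f), %d T1\n",
              nd, ne, if (nd > 0) ne / nd else NA, nt))
  cat(sprintf("  feedback: %s; heredity: %s; seed %d\n",
              x$config$feedback$mode,
              if (isTRUE(x$config$heredity$enabled))
                sprintf("q = %g", x$config$heredity$q) else "off",
              x$config$seed))
  invisible(x)
}

#' @export
summary.growth_run <- function(object, ...) {
  er <- elimination_rate(object)
  fit <- tissue_fitness(object)
  out <- list(
    n_initial = object$g[1], n_final = object$g[length(object$g)],
    t_final = max(object$times),
    n_divisions = sum(object$events$kind == "division"),
    n_eliminations = sum(object$events$kind == "t2"),
    n_t1 = sum(object$events$kind == "t1"),
    eps_mean = er$mean,
    phi_mean = mean(fit$phi, na.rm = TRUE),
    cv_size_mean = mean(object$stats$cv_size, na.rm = TRUE),
    var_stress_mean = mean(object$stats$var_stress, na.rm = TRUE))
  class(out) <- "summary.growth_run"
  out
}

#' @export
print.summary.growth_run <- function(x, ...) {
  cat(sprintf("growth %d -> %d cells in %.0f time units\n",
              x$n_initial, x$n_final, x$t_final))
  cat(sprintf("  divisions %d, eliminations %d, T1 %d\n",
              x$n_divisions, x$n_eliminations, x$n_t1))
  cat(sprintf("  temporal-mean elimination rate %.4f, fitness %.5f\n",
              x$eps_mean, x$phi_mean))
  cat(sprintf("  mean interior CV(size) %.3f, Var(stress magnitude) %.4f\n",
              x$cv_size_mean, x$var_stress_mean))
  invisible(x)
}

#' @export
plot.growth_run <- function(x, which = c("growth", "tissue"), ...) {
  which <- match.arg(which)
  if (which == "growth") {
    graphics::plot(x$times, x$g, type = "l", log = "y",
                   xlab = "time", ylab = "cells (log scale)", ...)
  } else {
    plot(x$tissue, fill = cell_areas(x$tissue),
         main = "final tissue (fill: cell area)", ...)
  }
  invisible(x)
}
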
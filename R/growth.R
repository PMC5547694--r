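## Cell cycle, division geometry, T1 rearrangement, T2 elimination and the
## growth-run orchestrator.

#' Advance the cell-cycle clocks
#'
#' Clocks run linearly with time, each at its own rate (1 by default; the
#' stress-gated feedback sets some rates to 0). Cells whose clock reaches
#' their cycle length enter mitosis: in \code{"ramp"} mode the mitotic flag is
#' raised and the current area snapshotted; in \code{"instant"} mode the cell
#' ids due to divide are returned in the \code{"divide_now"} attribute.
#'
#' @param tissue a tissue object.
#' @param dt elapsed time.
#' @param gate per-cell clock rate: a scalar, a vector, or a function of the
#'   cell index.
#' @param config a \code{\link{sim_config}}.
#' @return the updated tissue; attribute \code{"divide_now"} holds the indices
#'   of cells that must divide immediately (instant mode only).
#' @export
advance_clocks <- function(tissue, dt, gate = 1, config = sim_config()) {
  st <- tissue$state
  n <- length(tissue$cells)
  rate <- if (is.function(gate)) vapply(seq_len(n), gate, 0) else rep_len(gate, n)
  st$clock <- st$clock + rate * dt
  due <- which(st$clock >= st$cycle_len & !st$mitotic)
  divide_now <- integer(0)
  if (length(due)) {
    if (config$mitosis_mode == "instant") {
      divide_now <- due
    } else {
      a <- cell_areas(tissue)
      st$mitotic[due] <- TRUE
      st$pre_mitotic_area[due] <- a[due]
      st$mitotic_elapsed[due] <- 0
    }
  }
  tissue$state <- st
  attr(tissue, "divide_now") <- divide_now
  tissue
}

#' Mitotic natural-area growth
#'
#' During mitosis the natural area of a cell ramps up linearly; the cell
#' divides once its actual area reaches twice the area it had on entering
#' mitosis. Crowded cells that never double are forced to divide after
#' \code{mitosis_cap_mult} times the nominal ramp duration.
#'
#' @inheritParams advance_clocks
#' @return the tissue, with attribute \code{"divide_now"} listing the indices
#'   of mitotic cells ready to divide.
#' @export
mitotic_growth <- function(tissue, dt, config = sim_config()) {
  st <- tissue$state
  mit <- which(st$mitotic)
  attr(tissue, "divide_now") <- integer(0)
  if (!length(mit)) return(tissue)
  ramp_time <- config$mitosis_ramp_frac * config$cycle_len_mean
  rate <- if (is.finite(ramp_time) && ramp_time > 0) 1 / ramp_time else 0
  st$natural_area[mit] <- st$natural_area[mit] + rate * dt
  st$mitotic_elapsed[mit] <- st$mitotic_elapsed[mit] + dt
  tissue$state <- st
  a <- cell_areas(tissue)
  cap <- config$mitosis_cap_mult * ramp_time
  ready <- mit[a[mit] >= 2 * st$pre_mitotic_area[mit] |
                 (rate > 0 & st$mitotic_elapsed[mit] > cap)]
  attr(tissue, "divide_now") <- ready
  tissue
}

## ---- shape and division orientation ---------------------------------------

#' Shortest axis and shape anisotropy of a polygon
#'
#' Elliptical approximation of a cell from the second moments of its vertex
#' positions: the shortest axis is the minor principal axis of the vertex
#' scatter, and the shape anisotropy is one minus the ratio of the shortest to
#' the longest axis length.
#'
#' @param xy polygon vertex matrix (>= 3 rows).
#' @return list with \code{angle} (shortest-axis angle in [0, pi)),
#'   \code{long_angle} (major-axis angle), \code{anisotropy} in [0, 1), and
#'   \code{degenerate} (TRUE for a circularly symmetric vertex scatter).
#' @export
shortest_axis <- function(xy) {
  stopifnot(nrow(xy) >= 3)
  cx <- xy[, 1] - mean(xy[, 1]); cy <- xy[, 2] - mean(xy[, 2])
  sxx <- mean(cx * cx); syy <- mean(cy * cy); sxy <- mean(cx * cy)
  tr2 <- (sxx + syy) / 2
  r <- sqrt(((sxx - syy) / 2)^2 + sxy^2)
  l1 <- tr2 + r; l2 <- max(tr2 - r, 0)
  if (r < 1e-12 * max(tr2, 1e-300)) {
    return(list(angle = 0, long_angle = pi / 2, anisotropy = 0,
                degenerate = TRUE))
  }
  long <- atan2(2 * sxy, sxx - syy) / 2   # major-axis direction
  long <- long %% pi
  list(angle = (long + pi / 2) %% pi, long_angle = long,
       anisotropy = 1 - sqrt(l2 / l1), degenerate = FALSE)
}

## all cells at once: long-axis angle and anisotropy
cell_shape <- function(tissue) {
  ch <- cache_of(tissue)
  p <- tissue$pos
  x <- p[ch$cv, 1]; y <- p[ch$cv, 2]
  k <- ch$k[ch$cid]
  mx <- as.vector(rowsum(x, ch$cid)) / ch$k
  my <- as.vector(rowsum(y, ch$cid)) / ch$k
  cx <- x - mx[ch$cid]; cy <- y - my[ch$cid]
  sxx <- as.vector(rowsum(cx * cx, ch$cid)) / ch$k
  syy <- as.vector(rowsum(cy * cy, ch$cid)) / ch$k
  sxy <- as.vector(rowsum(cx * cy, ch$cid)) / ch$k
  tr2 <- (sxx + syy) / 2
  r <- sqrt(((sxx - syy) / 2)^2 + sxy^2)
  l1 <- tr2 + r; l2 <- pmax(tr2 - r, 0)
  data.frame(long_angle = (atan2(2 * sxy, sxx - syy) / 2) %% pi,
             anisotropy = ifelse(l1 > 0, 1 - sqrt(l2 / l1), 0))
}

#' Sample from the von Mises distribution
#'
#' Best-Fisher rejection sampler; \code{kappa = 0} degenerates to the uniform
#' distribution on (-pi, pi].
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @return numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u1 <- stats::runif(1); u2 <- stats::runif(1)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
        theta <- sign(stats::runif(1) - 0.5) * acos(f)
        out[i] <- (theta + mu + pi) %% (2 * pi) - pi
        break
      }
    }
  }
  out
}

#' Sample a division axis for a cell
#'
#' The division axis is the cell's shortest axis plus a von Mises deviation.
#' Axes are undirected (period pi), so the deviation is sampled on the doubled
#' angle and halved: \code{kappa = 0} gives an isotropic axis, large
#' \code{kappa} aligns division with the shortest axis.
#'
#' @param xy polygon vertex matrix of the dividing cell.
#' @param kappa von Mises concentration (>= 0).
#' @return axis angle in [0, pi).
#' @export
sample_division_axis <- function(xy, kappa = 0) {
  ax <- shortest_axis(xy)
  delta <- rvonmises(1, 0, kappa) / 2
  (ax$angle + delta) %% pi
}

## ---- division ---------------------------------------------------------------

## intersections of the line centroid + t * (cos a, sin a) with polygon edges;
## returns NULL when a clean two-sided pair cannot be found
chord_through <- function(xy, cen, angle) {
  k <- nrow(xy)
  j <- c(seq_len(k)[-1], 1L)
  d <- c(cos(angle), sin(angle))
  ex <- xy[j, 1] - xy[, 1]; ey <- xy[j, 2] - xy[, 2]
  wx <- cen[1] - xy[, 1];  wy <- cen[2] - xy[, 2]
  den <- ex * d[2] - ey * d[1]           # cross(e, d)
  s <- (wx * d[2] - wy * d[1]) / den     # cross(w, d) / cross(e, d)
  t <- (ex * wy - ey * wx) / den         # cross(e, w) / cross(e, d) = -cross(w,e)/..
  t <- -t
  ok <- is.finite(s) & s >= 1e-9 & s <= 1 - 1e-9
  pos_side <- ok & t > 0
  neg_side <- ok & t < 0
  if (!any(pos_side) || !any(neg_side)) return(NULL)
  e1 <- which(pos_side)[which.min(t[pos_side])]
  e2 <- which(neg_side)[which.max(t[neg_side])]
  list(edge = c(e1, e2), s = s[c(e1, e2)],
       p1 = c(xy[e1, 1] + s[e1] * ex[e1], xy[e1, 2] + s[e1] * ey[e1]),
       p2 = c(xy[e2, 1] + s[e2] * ex[e2], xy[e2, 2] + s[e2] * ey[e2]))
}

#' Divide a cell along a given axis
#'
#' Inserts a new edge through the cell centroid in direction \code{angle}.
#' Two new vertices appear where the axis crosses the cell boundary; the
#' neighbouring cells sharing the crossed edges gain one vertex each. The
#' daughters start a fresh cycle (clock 0, natural area 1, new cycle length);
#' traits are assigned by \code{\link{inherit_trait}} when heredity is on.
#' Pathological axes that fail to produce a two-sided chord are retried with a
#' perturbed angle.
#'
#' @param tissue a tissue object.
#' @param ci index of the dividing cell.
#' @param angle division-axis angle.
#' @param config a \code{\link{sim_config}}.
#' @return the updated tissue, with attribute \code{"event"} describing the
#'   division (or NULL if the division had to be abandoned).
#' @export
divide_cell <- function(tissue, ci, angle, config = sim_config()) {
  orig <- tissue
  v <- tissue$cells[[ci]]
  xy <- tissue$pos[v, , drop = FALSE]
  cen <- poly_centroid(xy)
  ch <- NULL
  for (try in 0:7) {
    ch <- chord_through(xy, cen, angle + try * 0.23)
    if (!is.null(ch)) break
  }
  attr(tissue, "event") <- NULL
  if (is.null(ch)) return(tissue)    # abandoned; caller logs
  k <- length(v)
  a1 <- ch$edge[1]; a2 <- ch$edge[2]
  w1p <- ch$p1; w2p <- ch$p2
  if (a1 > a2) { tmp <- a1; a1 <- a2; a2 <- tmp
                 tmp <- w1p; w1p <- w2p; w2p <- tmp }
  nv <- nrow(tissue$pos)
  w1 <- nv + 1L; w2 <- nv + 2L
  tissue$pos <- rbind(tissue$pos, w1p, w2p)
  rownames(tissue$pos) <- NULL
  segA <- v[(a1 + 1):a2]
  segB <- if (a2 < k) c(v[(a2 + 1):k], v[seq_len(a1)]) else v[seq_len(a1)]
  dA <- c(w1, segA, w2)
  dB <- c(w2, segB, w1)
  # insert the new vertices into the neighbours across the crossed edges
  cache <- cache_of(orig)
  nbs <- integer(0)
  for (q in 1:2) {
    va <- v[c(a1, a2)[q]]
    vb <- v[c(if (a1 < k) a1 + 1 else 1, if (a2 < k) a2 + 1 else 1)[q]]
    wq <- c(w1, w2)[q]
    slot <- which(cache$cv == vb & cache$v2 == va)
    slot <- slot[cache$cid[slot] != ci]
    if (length(slot) == 1) {
      nb <- cache$cid[slot]
      nbs <- c(nbs, nb)
      cyc <- tissue$cells[[nb]]
      at <- which(cyc == vb)[1]
      tissue$cells[[nb]] <- append(cyc, wq, after = at)
    }
  }
  st <- tissue$state
  hd <- config$heredity
  parent_trait <- st$trait[ci]
  parent_id <- st$id[ci]
  parent_area <- abs(poly_area(xy))
  mk_child <- function() {
    s <- list(lam = st$lam[ci], gam = st$gam[ci], trait = parent_trait,
              clock = 0,
              cycle_len = stats::runif(1,
                config$cycle_len_mean * (1 - config$cycle_jitter),
                config$cycle_len_mean * (1 + config$cycle_jitter)),
              natural_area = 1, mitotic = FALSE, pre_mitotic_area = NA_real_,
              mitotic_elapsed = 0, id = NA_integer_)
    if (isTRUE(hd$enabled) && !is.na(parent_trait)) {
      s$trait <- inherit_trait(parent_trait, hd$q, length(hd$grid))
      if (hd$param == "lam") s$lam <- hd$grid[s$trait]
      else s$gam <- hd$grid[s$trait]
    }
    s
  }
  c1 <- mk_child(); c2 <- mk_child()
  c1$id <- tissue$next_id; c2$id <- tissue$next_id + 1L
  tissue$next_id <- tissue$next_id + 2L
  tissue$cells[[ci]] <- dA
  tissue$cells[[length(tissue$cells) + 1L]] <- dB
  for (nm in names(st)) {
    st[[nm]][ci] <- c1[[nm]]
    st[[nm]][length(tissue$cells)] <- c2[[nm]]
  }
  tissue$state <- st
  attr(tissue, "cache") <- NULL
  if (!mesh_ok(tissue, c(ci, length(tissue$cells), nbs))) {
    attr(orig, "event") <- NULL   # abandoned: degenerate chord geometry
    return(orig)
  }
  attr(tissue, "event") <- list(parent_id = parent_id,
                                d1 = c1$id, d2 = c2$id,
                                x = cen[1], y = cen[2],
                                trait = parent_trait, area = parent_area,
                                d1_trait = c1$trait, d2_trait = c2$trait)
  tissue
}

## ---- T1 rearrangement -------------------------------------------------------

#' Sweep of T1 edge rearrangements
#'
#' Every interior edge shorter than \code{theta_T1} whose four surrounding
#' cells form a clean quartet is reconnected: the two cells sharing the edge
#' separate and the two cells at its endpoints become neighbours. The new edge
#' is perpendicular to the old one with length
#' \code{t1_expansion * theta_T1}. Boundary edges, edges whose endpoints are
#' not simple three-cell junctions, and edges on triangular cells are skipped.
#'
#' @param tissue a tissue object.
#' @param config a \code{\link{sim_config}} (uses \code{theta_T1} and
#'   \code{t1_expansion}).
#' @param theta_T1 override of the threshold.
#' @return the tissue; attribute \code{"n_t1"} counts rearrangements and
#'   \code{"t1_events"} holds their locations.
#' @export
apply_T1 <- function(tissue, config = sim_config(),
                     theta_T1 = config$theta_T1) {
  ch <- cache_of(tissue)
  p <- tissue$pos
  el <- sqrt((p[ch$v2, 1] - p[ch$cv, 1])^2 + (p[ch$v2, 2] - p[ch$cv, 2])^2)
  cand <- which(!ch$boundary_he & el < theta_T1 & ch$cid < ch$partner_cell)
  attr(tissue, "n_t1") <- 0L
  attr(tissue, "t1_events") <- list()
  if (!length(cand)) return(tissue)
  cand <- cand[order(el[cand])]
  vert_cells <- split(ch$cid, ch$cv)       # cells incident to each vertex
  touched <- rep(FALSE, ch$nv)
  events <- list()
  n_t1 <- 0L
  for (s in cand) {
    a <- ch$cv[s]; b <- ch$v2[s]
    if (touched[a] || touched[b]) next
    if (ch$boundary_vertex[a] || ch$boundary_vertex[b]) next
    alpha <- ch$cid[s]; beta <- ch$partner_cell[s]
    ca <- vert_cells[[as.character(a)]]
    cb <- vert_cells[[as.character(b)]]
    if (length(ca) != 3 || length(cb) != 3) next
    gamma <- setdiff(ca, c(alpha, beta))
    delta <- setdiff(cb, c(alpha, beta))
    if (length(gamma) != 1 || length(delta) != 1 || gamma == delta) next
    if (length(tissue$cells[[alpha]]) <= 3 ||
        length(tissue$cells[[beta]]) <= 3) next
    if (b %in% tissue$cells[[gamma]] || a %in% tissue$cells[[delta]]) next
    m <- (p[a, ] + p[b, ]) / 2
    dir <- (p[b, ] - p[a, ]) / sqrt(sum((p[b, ] - p[a, ])^2))
    perp <- c(-dir[2], dir[1])
    cen_a <- poly_centroid(p[tissue$cells[[alpha]], , drop = FALSE])
    if (sum(perp * (cen_a - m)) < 0) perp <- -perp
    h <- config$t1_expansion * theta_T1 / 2
    quartet <- c(alpha, beta, gamma, delta)
    saved_cells <- tissue$cells[quartet]
    saved_pos <- p[c(a, b), ]
    p[a, ] <- m + h * perp
    p[b, ] <- m - h * perp
    cyc <- tissue$cells[[alpha]]
    tissue$cells[[alpha]] <- cyc[cyc != b]
    cyc <- tissue$cells[[beta]]
    tissue$cells[[beta]] <- cyc[cyc != a]
    cyc <- tissue$cells[[gamma]]
    at <- which(cyc == a)
    tissue$cells[[gamma]] <- append(cyc, b, after = at - 1L)
    cyc <- tissue$cells[[delta]]
    at <- which(cyc == b)
    tissue$cells[[delta]] <- append(cyc, a, after = at - 1L)
    tissue$pos <- p
    attr(tissue, "cache") <- NULL
    if (!mesh_ok(tissue, quartet)) {      # revert a geometrically bad swap
      tissue$cells[quartet] <- saved_cells
      p[c(a, b), ] <- saved_pos
      tissue$pos <- p
      attr(tissue, "cache") <- NULL
      next
    }
    for (cc in quartet)
      touched[tissue$cells[[cc]]] <- TRUE
    n_t1 <- n_t1 + 1L
    events[[n_t1]] <- list(x = m[1], y = m[2], cells = quartet)
  }
  tissue$pos <- p
  attr(tissue, "cache") <- NULL
  attr(tissue, "n_t1") <- n_t1
  attr(tissue, "t1_events") <- events
  tissue
}

## ---- rosette resolution -------------------------------------------------------

#' Resolve multi-fold vertices
#'
#' Cell extrusion (and crowding) can leave vertices where four or more cells
#' meet. Such rosette vertices cannot take part in T1 rearrangements and
#' progressively jam the tissue, so each is resolved into three-fold vertices
#' by splitting: one incident cell is peeled off onto its own vertex, a short
#' new edge (length \code{t1_expansion * theta_T1}) is created between the two
#' flanking cells, and the process repeats until every junction is three-fold.
#' Splits whose local mesh fails validation are skipped (and retried after
#' further relaxation).
#'
#' @param tissue a tissue object.
#' @param config a \code{\link{sim_config}}.
#' @return the tissue; attribute \code{"n_resolved"} counts splits.
#' @export
resolve_rosettes <- function(tissue, config = sim_config()) {
  n_res <- 0L
  repeat {
    ch <- cache_of(tissue)
    vc <- split(seq_along(ch$cv), ch$cv)       # slots per vertex
    deg <- lengths(vc)
    high <- as.integer(names(vc))[deg >= 4 & !ch$boundary_vertex[
      as.integer(names(vc))]]
    if (!length(high)) break
    progress <- FALSE
    for (w in high) {
      slots <- vc[[as.character(w)]]
      cells_at <- ch$cid[slots]
      k <- length(cells_at)
      if (k < 4) next
      ## cyclic fan: from each incident cell step across the edge (w -> next)
      nxt_cell <- ch$partner_cell[slots]       # cell across edge w->next(w)
      if (anyNA(nxt_cell)) next
      fan <- integer(k)
      fan[1] <- cells_at[1]
      for (q in 2:k) {
        fan[q] <- nxt_cell[match(fan[q - 1], cells_at)]
        if (is.na(fan[q]) || fan[q] %in% fan[seq_len(q - 1)]) break
      }
      if (anyNA(fan) || length(unique(fan)) != k) next
      a <- cell_areas(tissue)
      for (A in fan[order(-a[fan])]) {
        ia <- match(A, fan)
        B <- fan[if (ia == 1) k else ia - 1]
        D <- fan[if (ia == k) 1 else ia + 1]
        saved_cells <- tissue$cells[c(A, B, D)]
        saved_nv <- nrow(tissue$pos)
        cenA <- poly_centroid(tissue$pos[tissue$cells[[A]], , drop = FALSE])
        dir <- cenA - tissue$pos[w, ]
        nd <- sqrt(sum(dir^2))
        if (nd < 1e-12) next
        dir <- dir / nd
        h <- config$t1_expansion * config$theta_T1 / 2
        w1 <- saved_nv + 1L
        tissue$pos <- rbind(tissue$pos, tissue$pos[w, ] + 2 * h * dir)
        rownames(tissue$pos) <- NULL
        # A moves to the new vertex; B and D gain it next to w, closing the
        # fan with the new short edge (w1, w)
        cycA <- tissue$cells[[A]]
        cycA[cycA == w] <- w1
        tissue$cells[[A]] <- cycA
        cycB <- tissue$cells[[B]]
        atB <- which(cycB == w)
        tissue$cells[[B]] <- append(cycB, w1, after = atB)
        cycD <- tissue$cells[[D]]
        atD <- which(cycD == w)
        tissue$cells[[D]] <- append(cycD, w1, after = atD - 1L)
        attr(tissue, "cache") <- NULL
        if (mesh_ok(tissue, c(A, B, D))) {
          n_res <- n_res + 1L
          progress <- TRUE
          break
        }
        tissue$cells[c(A, B, D)] <- saved_cells
        tissue$pos <- tissue$pos[seq_len(saved_nv), , drop = FALSE]
        attr(tissue, "cache") <- NULL
      }
      if (progress) break   # topology changed: rebuild bookkeeping
    }
    if (!progress) break
  }
  attr(tissue, "n_resolved") <- n_res
  tissue
}

## ---- T2 elimination ---------------------------------------------------------

#' Sweep of T2 cell eliminations
#'
#' Every cell whose area is below \code{theta_T2} is collapsed onto a single
#' vertex at its centroid; the neighbouring cells absorb the collapse by
#' replacing their shared vertices with the new one. Rare neighbours reduced
#' below three vertices by the collapse are removed in cascade (and logged as
#' eliminations as well).
#'
#' @param tissue a tissue object.
#' @param config a \code{\link{sim_config}}.
#' @param theta_T2 override of the area threshold.
#' @return the tissue; attribute \code{"t2_events"} is a list with one entry
#'   per eliminated cell (id, last area, location, trait).
#' @export
apply_T2 <- function(tissue, config = sim_config(),
                     theta_T2 = config$theta_T2) {
  a <- cell_areas(tissue)
  cand <- which(a < theta_T2)
  attr(tissue, "t2_events") <- list()
  if (!length(cand)) return(tissue)
  cand <- cand[order(a[cand])]
  touched <- rep(FALSE, nrow(tissue$pos))
  removed <- rep(FALSE, length(tissue$cells))
  events <- list()
  for (ci in cand) {
    if (removed[ci]) next
    vs <- tissue$cells[[ci]]
    if (any(touched[vs])) next
    saved_cells <- tissue$cells
    saved_removed <- removed
    saved_nv <- nrow(tissue$pos)
    xy <- tissue$pos[vs, , drop = FALSE]
    cen <- poly_centroid(xy)
    w <- nrow(tissue$pos) + 1L
    tissue$pos <- rbind(tissue$pos, cen)
    rownames(tissue$pos) <- NULL
    this_events <-
      list(list(id = tissue$state$id[ci], area = poly_area(xy),
                x = cen[1], y = cen[2], trait = tissue$state$trait[ci],
                cascade = FALSE))
    removed[ci] <- TRUE
    new_touch <- integer(0)
    modified <- integer(0)
    for (oc in seq_along(tissue$cells)) {
      if (removed[oc]) next
      cyc <- tissue$cells[[oc]]
      if (!any(cyc %in% vs)) next
      cyc[cyc %in% vs] <- w
      cyc <- cyc[c(TRUE, cyc[-1] != cyc[-length(cyc)])]
      if (length(cyc) > 1 && cyc[1] == cyc[length(cyc)])
        cyc <- cyc[-length(cyc)]
      if (length(cyc) < 3) {
        removed[oc] <- TRUE
        this_events[[length(this_events) + 1L]] <-
          list(id = tissue$state$id[oc],
               area = a[oc], x = cen[1], y = cen[2],
               trait = tissue$state$trait[oc], cascade = TRUE)
        next
      }
      tissue$cells[[oc]] <- cyc
      new_touch <- c(new_touch, cyc)
      modified <- c(modified, oc)
    }
    ## integrity: the collapse must leave a consistent mesh with positive
    ## areas on the remodelled neighbours
    probe <- tissue
    keep <- !removed
    probe$cells <- probe$cells[keep]
    probe$state <- lapply(probe$state, function(x) x[keep])
    if (length(probe$cells) >= 1 &&
        !mesh_ok(probe, cumsum(keep)[modified])) {
      tissue$cells <- saved_cells
      removed <- saved_removed
      tissue$pos <- tissue$pos[seq_len(saved_nv), , drop = FALSE]
      touched[vs] <- TRUE       # do not retry within this sweep
      next
    }
    for (e in this_events) events[[length(events) + 1L]] <- e
    touched[new_touch] <- TRUE
    touched[w] <- TRUE
    touched[vs] <- TRUE
  }
  if (any(removed)) {
    keep <- !removed
    tissue$cells <- tissue$cells[keep]
    tissue$state <- lapply(tissue$state, function(x) x[keep])
    tissue <- compact_tissue(tissue)
  }
  attr(tissue, "cache") <- NULL
  attr(tissue, "t2_events") <- events
  tissue
}
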
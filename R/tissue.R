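#' Construct a tissue object
#'
#' A tissue is a planar polygonal mesh: a matrix of vertex positions and a
#' list of cells, each an ordered (counter-clockwise) cycle of vertex indices.
#' Interior edges are shared by exactly two cells, boundary edges by one.
#' Per-cell mechanical state travels alongside the mesh.
#'
#' @param pos numeric matrix (n_vertices x 2) of vertex positions.
#' @param cells list of integer vectors, counter-clockwise vertex cycles.
#' @param state optional list of per-cell vectors (\code{lam}, \code{gam},
#'   \code{trait}, \code{clock}, \code{cycle_len}, \code{natural_area},
#'   \code{mitotic}, \code{pre_mitotic_area}, \code{id}); missing entries get
#'   defaults from \code{config}.
#' @param config a \code{\link{sim_config}} supplying default parameters.
#' @return an object of class \code{tissue}.
#' @export
new_tissue <- function(pos, cells, state = NULL, config = sim_config()) {
  pos <- as.matrix(pos)
  storage.mode(pos) <- "double"
  stopifnot(ncol(pos) == 2, is.list(cells), length(cells) >= 1)
  cells <- lapply(cells, as.integer)
  nc <- length(cells)
  def <- list(
    lam = rep(config$lam0, nc),
    gam = rep(config$gam0, nc),
    trait = rep(NA_integer_, nc),
    clock = rep(0, nc),
    cycle_len = rep(config$cycle_len_mean, nc),
    natural_area = rep(1, nc),
    mitotic = rep(FALSE, nc),
    pre_mitotic_area = rep(NA_real_, nc),
    mitotic_elapsed = rep(0, nc),
    id = seq_len(nc)
  )
  if (!is.null(state)) for (nm in names(state)) def[[nm]] <- state[[nm]]
  tis <- list(pos = pos, cells = cells, state = def,
              next_id = max(def$id) + 1L)
  class(tis) <- "tissue"
  tis
}

#' @export
print.tissue <- function(x, ...) {
  ca <- cell_areas(x)
  cat(sprintf("tissue: %d cells, %d vertices\n", length(x$cells), nrow(x$pos)))
  cat(sprintf("  area: mean %.3f, CV %.3f; polygon classes: %s\n",
              mean(ca), stats::sd(ca) / mean(ca),
              paste(names(table(lengths(x$cells))), collapse = "/")))
  invisible(x)
}

#' @export
plot.tissue <- function(x, fill = NULL, main = NULL, ...) {
  graphics::plot(x$pos, type = "n", asp = 1, xlab = "", ylab = "",
                 main = main, ...)
  cols <- if (is.null(fill)) NA else
    grDevices::hcl.colors(100, "viridis")[
      cut(fill, breaks = 100, labels = FALSE, include.lowest = TRUE)]
  for (i in seq_along(x$cells)) {
    v <- x$cells[[i]]
    graphics::polygon(x$pos[v, 1], x$pos[v, 2],
                      col = if (is.null(fill)) NA else cols[i],
                      border = "grey30", lwd = 0.4)
  }
  invisible(x)
}

## ---- geometry cache -------------------------------------------------------
## Flat half-edge arrays rebuilt only when topology changes. Slot s is the
## half-edge from vertex cv[s] to cv[nxt[s]] inside cell cid[s].
build_cache <- function(tissue) {
  cells <- tissue$cells
  k <- lengths(cells)
  if (any(k < 3)) stop("invalid mesh: cell with fewer than 3 vertices")
  cv <- unlist(cells, use.names = FALSE)
  nc <- length(cells)
  cid <- rep.int(seq_len(nc), k)
  ends <- cumsum(k)
  starts <- ends - k + 1L
  idx <- seq_along(cv)
  nxt <- idx + 1L
  nxt[ends] <- starts
  prv <- idx - 1L
  prv[starts] <- ends
  v1 <- cv
  v2 <- cv[nxt]
  if (any(v1 == v2)) stop("invalid mesh: zero-length edge in a cell cycle")
  nv <- nrow(tissue$pos)
  key <- pmin(v1, v2) * (nv + 1) + pmax(v1, v2)
  o <- order(key)
  ko <- key[o]
  n <- length(ko)
  partner <- rep(NA_integer_, n)
  runs <- rle(ko)
  if (any(runs$lengths > 2))
    stop("invalid mesh: edge shared by more than two cells")
  first <- cumsum(runs$lengths) - runs$lengths + 1L
  two <- first[runs$lengths == 2L]
  if (length(two)) {
    partner[o[two]] <- o[two + 1L]
    partner[o[two + 1L]] <- o[two]
  }
  boundary_he <- is.na(partner)
  bnd_vertex <- rep(FALSE, nv)
  bnd_vertex[cv[boundary_he]] <- TRUE
  bnd_vertex[v2[boundary_he]] <- TRUE
  partner_cell <- rep(NA_integer_, n)
  partner_cell[!boundary_he] <- cid[partner[!boundary_he]]
  bnd_cell <- rep(FALSE, nc)
  bnd_cell[cid[boundary_he]] <- TRUE
  list(cv = cv, cid = cid, nxt = nxt, prv = prv, v2 = v2,
       partner = partner, partner_cell = partner_cell,
       boundary_he = boundary_he, boundary_vertex = bnd_vertex,
       boundary_cell = bnd_cell, nc = nc, nv = nv, k = k)
}

cache_of <- function(tissue) {
  ch <- attr(tissue, "cache")
  if (is.null(ch) || ch$nc != length(tissue$cells) ||
      ch$nv != nrow(tissue$pos)) ch <- build_cache(tissue)
  ch
}

with_cache <- function(tissue) {
  attr(tissue, "cache") <- build_cache(tissue)
  tissue
}

## per-half-edge line tension coefficient; internal half-edges carry half the
## effective pair tension so that summing both half-edges counts the edge once
he_tension <- function(cache, lam, config) {
  lt <- numeric(length(cache$cv))
  int <- !cache$boundary_he
  lt[int] <- effective_line_tension(lam[cache$cid[int]],
                                    lam[cache$partner_cell[int]],
                                    config$lam_combination) / 2
  lt[!int] <- config$boundary_tension_mult * lam[cache$cid[!int]]
  lt
}

## ---- areas / perimeters / centroids --------------------------------------

#' Cell areas, perimeters and centroids
#'
#' Signed polygon areas (positive under the counter-clockwise convention),
#' perimeters and area centroids of every cell.
#'
#' @param tissue a \code{\link{new_tissue}} object.
#' @return \code{cell_areas} and \code{cell_perimeters} return a numeric
#'   vector; \code{cell_centroids} an n x 2 matrix.
#' @export
cell_areas <- function(tissue) {
  ch <- cache_of(tissue)
  p <- tissue$pos
  cr <- p[ch$cv, 1] * p[ch$v2, 2] - p[ch$v2, 1] * p[ch$cv, 2]
  as.vector(rowsum(cr, ch$cid)) / 2
}

#' @rdname cell_areas
#' @export
cell_perimeters <- function(tissue) {
  ch <- cache_of(tissue)
  p <- tissue$pos
  el <- sqrt((p[ch$v2, 1] - p[ch$cv, 1])^2 + (p[ch$v2, 2] - p[ch$cv, 2])^2)
  as.vector(rowsum(el, ch$cid))
}

#' @rdname cell_areas
#' @export
cell_centroids <- function(tissue) {
  ch <- cache_of(tissue)
  p <- tissue$pos
  x1 <- p[ch$cv, 1]; y1 <- p[ch$cv, 2]
  x2 <- p[ch$v2, 1]; y2 <- p[ch$v2, 2]
  cr <- x1 * y2 - x2 * y1
  a <- as.vector(rowsum(cr, ch$cid)) / 2
  cx <- as.vector(rowsum((x1 + x2) * cr, ch$cid)) / (6 * a)
  cy <- as.vector(rowsum((y1 + y2) * cr, ch$cid)) / (6 * a)
  cbind(cx, cy)
}

## single polygon helpers (matrix of vertices, CCW)
poly_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(seq_len(nrow(xy))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}
poly_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(seq_len(nrow(xy))[-1], 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-9) return(c(mean(x), mean(y)))  # near-degenerate polygon
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

## ---- energy and forces ----------------------------------------------------

#' Tissue mechanical energy
#'
#' The dimensionless vertex-model energy
#' \deqn{U = \sum_\alpha \tfrac12 (A_\alpha - A_{0,\alpha})^2 +
#'       \sum_{<\alpha\beta>} \Lambda_{\alpha\beta} l_{\alpha\beta} +
#'       \sum_\alpha \tfrac{\Gamma_\alpha}{2} L_\alpha^2,}
#' with the natural area 1 outside mitosis. Edges between cells of different
#' traits use the combined tension (\code{max} or \code{mean}); boundary edges
#' carry \code{boundary_tension_mult} times the cell's own tension.
#'
#' @param tissue a tissue object.
#' @param config a \code{\link{sim_config}}.
#' @return scalar energy.
#' @export
compute_energy <- function(tissue, config = sim_config()) {
  ch <- cache_of(tissue)
  p <- tissue$pos
  st <- tissue$state
  a <- cell_areas(tissue)
  if (any(abs(a) < 1e-12)) stop("invalid mesh: degenerate (zero-area) cell")
  el <- sqrt((p[ch$v2, 1] - p[ch$cv, 1])^2 + (p[ch$v2, 2] - p[ch$cv, 2])^2)
  L <- as.vector(rowsum(el, ch$cid))
  lt <- he_tension(ch, st$lam, config)
  sum((a - st$natural_area)^2) / 2 + sum(lt * el) + sum(st$gam / 2 * L^2)
}

#' Vertex forces
#'
#' Analytic gradient forces \eqn{-\partial U / \partial r_i} for every vertex:
#' area elasticity, edge tension and perimeter contractility contributions.
#'
#' @inheritParams compute_energy
#' @return numeric matrix (n_vertices x 2).
#' @export
compute_forces <- function(tissue, config = sim_config()) {
  ch <- cache_of(tissue)
  vm_forces(tissue$pos, tissue$state, ch, config)
}

vm_forces <- function(p, st, ch, config, lt = NULL) {
  cv <- ch$cv; cid <- ch$cid; v2 <- ch$v2; prv <- ch$prv
  if (!length(cv)) stop("tissue collapsed: no cells left")
  if (is.null(lt)) lt <- he_tension(ch, st$lam, config)
  x1 <- p[cv, 1]; y1 <- p[cv, 2]
  x2 <- p[v2, 1]; y2 <- p[v2, 2]
  ex <- x2 - x1; ey <- y2 - y1
  el <- sqrt(ex * ex + ey * ey)
  # floor near-degenerate edges: forces stay bounded and the next T1/T2
  # sweep removes the edge itself
  el <- pmax(el, 1e-9)
  cr <- x1 * y2 - x2 * y1
  a <- as.vector(rowsum(cr, cid)) / 2
  L <- as.vector(rowsum(el, cid))
  ux <- ex / el; uy <- ey / el           # unit vector slot vertex -> next
  pux <- ux[prv]; puy <- uy[prv]         # unit vector prev vertex -> slot
  # area term: -(A - A0) * dA/dr_i, dA/dr_i = ((y_next - y_prev)/2, (x_prev - x_next)/2)
  pa <- -(a - st$natural_area)[cid]
  xp <- x1[prv]; yp <- y1[prv]           # prev slot shares the cell ordering
  fax <- pa * (y2 - yp) / 2
  fay <- pa * (xp - x2) / 2
  # perimeter term: -Gamma L (u_in + u_out) with u_in = (r_i - r_prev)/|.|,
  # u_out = (r_i - r_next)/|.|
  gl <- -(st$gam * L)[cid]
  fpx <- gl * (pux - ux)
  fpy <- gl * (puy - uy)
  # line tension: each incident half edge pulls the vertex toward the far end
  ftx <- lt * ux - lt[prv] * pux
  fty <- lt * uy - lt[prv] * puy
  fs <- cbind(fax + fpx + ftx, fay + fpy + fty)
  rs <- rowsum(fs, cv)
  if (nrow(rs) == nrow(p)) {     # every vertex used: rows already 1..nv
    dimnames(rs) <- NULL
    return(rs)
  }
  f <- matrix(0, nrow(p), 2)
  f[as.integer(rownames(rs)), ] <- rs
  f
}

#' Effective line tension of an edge between two cells
#'
#' Combines the per-cell tension coefficients of the two cells sharing an
#' edge, either as the maximum (default; adhesion limited by the weaker
#' partner) or the arithmetic mean.
#'
#' @param lam_a,lam_b non-negative tension coefficients (vectorised).
#' @param mode \code{"max"} or \code{"mean"}.
#' @return combined coefficient(s).
#' @export
effective_line_tension <- function(lam_a, lam_b, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  if (any(lam_a < 0) || any(lam_b < 0))
    stop("line-tension coefficients must be non-negative")
  if (mode == "max") pmax(lam_a, lam_b) else (lam_a + lam_b) / 2
}

#' One explicit Euler step of the overdamped vertex dynamics
#'
#' Moves every vertex by \code{dt / eta} times its force. Purely positional:
#' no topological change happens here.
#'
#' @inheritParams compute_energy
#' @param dt step size, at most \code{config$dt}.
#' @return the tissue with updated vertex positions.
#' @export
step_vertices <- function(tissue, config = sim_config(), dt = config$dt) {
  stopifnot(dt <= config$dt)
  if (dt == 0) return(tissue)
  ch <- cache_of(tissue)
  f <- vm_forces(tissue$pos, tissue$state, ch, config)
  tissue$pos <- tissue$pos + (dt / config$eta) * f
  attr(tissue, "cache") <- ch
  tissue
}

#' Relax a tissue toward mechanical equilibrium
#'
#' Iterates \code{\link{step_vertices}} until the maximum vertex-force norm
#' drops below \code{force_tol} or \code{max_steps} is reached. Under the
#' quasi-static assumption the tissue is relaxed between growth events. Per
#' step displacements are clamped at \code{config$max_disp} so that an edge
#' being crushed cannot fling its vertices across each other; with
#' \code{t1_sweeps = TRUE}, T1 rearrangements are swept periodically during
#' the descent, which is how sub-threshold edges are meant to resolve.
#'
#' @inheritParams compute_energy
#' @param force_tol convergence threshold on the max vertex-force norm.
#' @param max_steps iteration cap.
#' @param t1_sweeps interleave \code{\link{apply_T1}} sweeps every
#'   \code{t1_every} steps.
#' @param t1_every sweep period in steps.
#' @param dilate accelerate the slowest collective mode (uniform dilation,
#'   whose viscous timescale grows with tissue area) by an exact line search
#'   over a global scale factor about the tissue centroid; the tissue energy
#'   is a closed-form function of the scale, so the optimal factor is the
#'   root of a cubic and the move is strictly energy-decreasing.
#' @return the relaxed tissue; attributes \code{converged} (logical),
#'   \code{steps}, \code{n_t1} and \code{t1_events} report the outcome.
#' @export
relax <- function(tissue, config = sim_config(),
                  force_tol = config$relax_force_tol,
                  max_steps = config$relax_max_steps,
                  t1_sweeps = FALSE, t1_every = 20L,
                  dilate = isTRUE(config$dilate)) {
  ch <- cache_of(tissue)
  p <- tissue$pos
  dt <- config$dt / config$eta
  steps <- 0L
  converged <- FALSE
  n_t1 <- 0L
  t1_events <- list()
  lt <- he_tension(ch, tissue$state$lam, config)  # topology-fixed within loop
  repeat {
    f <- vm_forces(p, tissue$state, ch, config, lt)
    if (sqrt(max(f[, 1]^2 + f[, 2]^2)) < force_tol) {
      converged <- TRUE
      break
    }
    if (steps >= max_steps) break
    dx <- dt * f
    dn <- sqrt(dx[, 1]^2 + dx[, 2]^2)
    over <- dn > config$max_disp
    if (any(over)) dx[over, ] <- dx[over, ] * (config$max_disp / dn[over])
    p <- p + dx
    steps <- steps + 1L
    if (dilate && steps %% 10L == 0L)
      p <- dilate_to_minimum(p, tissue$state, ch, config, lt)
    if (t1_sweeps && steps %% t1_every == 0L) {
      tissue$pos <- p
      attr(tissue, "cache") <- ch
      tissue <- apply_T1(tissue, config)
      k <- attr(tissue, "n_t1")
      if (k > 0L) {
        n_t1 <- n_t1 + k
        t1_events <- c(t1_events, attr(tissue, "t1_events"))
        ch <- build_cache(tissue)
        lt <- he_tension(ch, tissue$state$lam, config)
      }
      p <- tissue$pos
    }
  }
  tissue$pos <- p
  attr(tissue, "cache") <- ch
  attr(tissue, "converged") <- converged
  attr(tissue, "steps") <- steps
  attr(tissue, "n_t1") <- n_t1
  attr(tissue, "t1_events") <- t1_events
  tissue
}

## ---- validation -----------------------------------------------------------

#' Validate mesh invariants
#'
#' Checks that every cell has at least three distinct vertices and positive
#' signed area, that each edge belongs to one or two cells, and (optionally)
#' that every polygon is simple.
#'
#' @param tissue a tissue object.
#' @param check_simple also test polygons for self-intersection (quadratic in
#'   polygon size; meant for tests and fixtures).
#' @return invisibly \code{TRUE}; stops with a message on violation.
#' @export
validate_tissue <- function(tissue, check_simple = FALSE) {
  if (length(tissue$state$lam) != length(tissue$cells))
    stop("state length does not match cell count")
  ch <- build_cache(tissue)   # errors on >2 incidence / <3 vertices
  if (any(vapply(tissue$cells, anyDuplicated, 1L) > 0))
    stop("invalid mesh: repeated vertex in a cell cycle")
  a <- cell_areas(tissue)
  if (any(a <= 0))
    stop("invalid mesh: non-positive signed area (orientation must be CCW)")
  if (check_simple) {
    for (i in seq_along(tissue$cells)) {
      if (!polygon_is_simple(tissue$pos[tissue$cells[[i]], , drop = FALSE]))
        stop(sprintf("invalid mesh: cell %d is self-intersecting", i))
    }
  }
  invisible(TRUE)
}

polygon_is_simple <- function(xy) {
  n <- nrow(xy)
  if (n < 4) return(TRUE)
  j <- c(seq_len(n)[-1], 1L)
  for (e1 in seq_len(n - 2)) {
    for (e2 in (e1 + 2):n) {
      if (e1 == 1 && e2 == n) next  # adjacent around the wrap
      if (segments_cross(xy[e1, ], xy[j[e1], ], xy[e2, ], xy[j[e2], ]))
        return(FALSE)
    }
  }
  TRUE
}

segments_cross <- function(a, b, c, d) {
  o <- function(p, q, r) sign((q[1] - p[1]) * (r[2] - p[2]) -
                              (q[2] - p[2]) * (r[1] - p[1]))
  o(a, b, c) != o(a, b, d) && o(c, d, a) != o(c, d, b) &&
    o(a, b, c) != 0 && o(c, d, a) != 0
}

## cell adjacency as a list id-indexed by position: neighbors of each cell
cell_adjacency <- function(tissue) {
  ch <- cache_of(tissue)
  int <- !ch$boundary_he
  pairs <- unique(cbind(ch$cid[int], ch$partner_cell[int]))
  adj <- vector("list", ch$nc)
  sp <- split(pairs[, 2], pairs[, 1])
  adj[as.integer(names(sp))] <- sp
  adj
}

## exact line search over a uniform scale factor s about the tissue centroid:
## U(s) = sum (s^2 A - A0)^2 / 2 + s * c1 + s^2 * c2 with c1 the tension and
## c2 the contractility coefficients; dU/ds is a cubic solved for its root
## near 1. Restricted to a trust region so topology-scale assumptions hold.
dilate_to_minimum <- function(p, st, ch, config, lt = NULL) {
  cen <- colMeans(p)
  x1 <- p[ch$cv, 1]; y1 <- p[ch$cv, 2]
  x2 <- p[ch$v2, 1]; y2 <- p[ch$v2, 2]
  a <- as.vector(rowsum(x1 * y2 - x2 * y1, ch$cid)) / 2
  el <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  L <- as.vector(rowsum(el, ch$cid))
  if (is.null(lt)) lt <- he_tension(ch, st$lam, config)
  c1 <- sum(lt * el)
  c2 <- sum(st$gam / 2 * L^2)
  a0 <- st$natural_area
  dU <- function(s) 2 * s^3 * sum(a^2) - 2 * s * sum(a * a0) + c1 + 2 * s * c2
  lo <- 0.95; hi <- 1.05
  dlo <- dU(lo); dhi <- dU(hi)
  s <- if (dlo >= 0 && dhi >= 0) lo         # U increasing across the region
  else if (dlo <= 0 && dhi <= 0) hi         # U decreasing across the region
  else stats::uniroot(dU, c(lo, hi), tol = 1e-10)$root
  if (abs(s - 1) < 1e-12) return(p)
  sweep(sweep(p, 2, cen, "-") * s, 2, cen, "+")
}

## fast integrity check used by the topological operators: cache buildable
## (every edge in <= 2 cells, >= 3 vertices per cell) and positive areas on
## the touched cells
mesh_ok <- function(tissue, cells_idx = NULL) {
  ch <- tryCatch(build_cache(tissue), error = function(e) NULL)
  if (is.null(ch)) return(FALSE)
  if (any(vapply(tissue$cells, anyDuplicated, 1L) > 0)) return(FALSE)
  idx <- if (is.null(cells_idx)) seq_along(tissue$cells) else cells_idx
  for (i in idx) {
    if (poly_area(tissue$pos[tissue$cells[[i]], , drop = FALSE]) <= 0)
      return(FALSE)
  }
  TRUE
}

## drop vertices not referenced by any cell and renumber
compact_tissue <- function(tissue) {
  used <- sort(unique(unlist(tissue$cells, use.names = FALSE)))
  if (length(used) == nrow(tissue$pos)) return(tissue)
  map <- integer(nrow(tissue$pos))
  map[used] <- seq_along(used)
  tissue$pos <- tissue$pos[used, , drop = FALSE]
  tissue$cells <- lapply(tissue$cells, function(v) map[v])
  attr(tissue, "cache") <- NULL
  tissue
}
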
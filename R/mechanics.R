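## Per-cell discrete Cauchy stress tensors and geometric/spatial statistics.

#' Cell pressure
#'
#' Dimensionless pressure \eqn{P_\alpha = -(A_\alpha - 1)}: a compressed cell
#' (A < 1) pushes outward with positive pressure. The stress metrics use the
#' unit natural area throughout — the transient mitotic ramp of the natural
#' area belongs to the growth dynamics, not to the stress read-out.
#'
#' @param tissue a tissue object.
#' @return numeric vector of per-cell pressures.
#' @export
cell_pressure <- function(tissue) {
  -(cell_areas(tissue) - 1)
}

#' Edge tensions
#'
#' Per-cell tension share of every edge,
#' \eqn{T_{ij,\alpha} = \Lambda_{\alpha\beta}/2 + \Gamma_\alpha L_\alpha};
#' the total tension of an interior edge is the sum of the shares of its two
#' incident cells. Boundary edges have a single incident cell which carries
#' the full (tripled) line tension.
#'
#' @param tissue a tissue object.
#' @param config a \code{\link{sim_config}}.
#' @return data frame with one row per half-edge: \code{cell}, \code{v1},
#'   \code{v2}, \code{length}, \code{share} (this cell's tension share),
#'   \code{boundary}.
#' @export
edge_tensions <- function(tissue, config = sim_config()) {
  ch <- cache_of(tissue)
  p <- tissue$pos
  st <- tissue$state
  el <- sqrt((p[ch$v2, 1] - p[ch$cv, 1])^2 + (p[ch$v2, 2] - p[ch$cv, 2])^2)
  L <- as.vector(rowsum(el, ch$cid))
  share <- he_tension(ch, st$lam, config) + st$gam[ch$cid] * L[ch$cid]
  data.frame(cell = ch$cid, v1 = ch$cv, v2 = ch$v2, length = el,
             share = share, boundary = ch$boundary_he)
}

#' Per-cell stress tensors
#'
#' Two discrete representations of the Cauchy stress of every cell, both built
#' from the cell pressure and the per-cell edge-tension shares under the
#' quasi-static assumption.
#'
#' Method \code{"A"} integrates the linearly interpolated vertex forces around
#' the cell boundary: \eqn{\sigma^{(A)} = \mathrm{sym}(\oint F \otimes r)/A}
#' with vertex forces composed of the pressure acting on the half-segment
#' between the vertex's two neighbours and the tension shares along the two
#' incident edges; positions are measured from the cell centroid.
#'
#' Method \code{"B"} sums edge dyads:
#' \eqn{\sigma^{(B)} = -P I + \sum_{edges} (T_{ij,\alpha}/A)\,
#' r_{ij}\otimes r_{ij} / \lVert r_{ij}\rVert}.
#'
#' @param tissue a tissue object.
#' @param config a \code{\link{sim_config}}.
#' @param method \code{"A"} or \code{"B"}.
#' @return data frame with one row per cell: tensor components (\code{sxx},
#'   \code{sxy}, \code{syy}), principal stresses \code{sigma1 >= sigma2},
#'   \code{magnitude} (\eqn{\sigma_1+\sigma_2}), \code{anisotropy}
#'   (\eqn{\sigma_1-\sigma_2}), \code{orientation} of the maximum principal
#'   stress in [0, pi), and \code{boundary}.
#' @export
cell_stress <- function(tissue, config = sim_config(), method = c("B", "A")) {
  method <- match.arg(method)
  ch <- cache_of(tissue)
  p <- tissue$pos
  st <- tissue$state
  x1 <- p[ch$cv, 1]; y1 <- p[ch$cv, 2]
  x2 <- p[ch$v2, 1]; y2 <- p[ch$v2, 2]
  ex <- x2 - x1; ey <- y2 - y1
  el <- sqrt(ex * ex + ey * ey)
  cr <- x1 * y2 - x2 * y1
  A <- as.vector(rowsum(cr, ch$cid)) / 2
  bad <- A <= 1e-12
  if (all(bad)) stop("invalid mesh: no cell with positive area")
  A[bad] <- NA_real_   # transiently inverted cells carry no defined stress
  L <- as.vector(rowsum(el, ch$cid))
  P <- -(A - 1)            # stress metrics use the unit natural area
  tshare <- he_tension(ch, st$lam, config) + st$gam[ch$cid] * L[ch$cid]
  if (method == "B") {
    w <- tshare / (A[ch$cid] * el)
    sxx <- as.vector(rowsum(w * ex * ex, ch$cid)) - P
    syy <- as.vector(rowsum(w * ey * ey, ch$cid)) - P
    sxy <- as.vector(rowsum(w * ex * ey, ch$cid))
  } else {
    cen <- cell_centroids(tissue)
    rx <- x1 - cen[ch$cid, 1]; ry <- y1 - cen[ch$cid, 2]
    # vertex forces (Fx, Fy) per slot: pressure along the outward normal of
    # the prev->next segment (scaled by half its length) plus tension shares
    # along the two incident edges
    prv <- ch$prv
    xp <- x1[prv]; yp <- y1[prv]
    xn <- x2;      yn <- y2          # next vertex
    gx <- xn - xp; gy <- yn - yp     # segment joining the two neighbours
    # outward normal of a CCW polygon is (gy, -gx)/|g|, scaled by |g|/2 so the
    # pressure forces integrate P over the whole boundary; tension shares pull
    # the vertex toward each adjacent vertex
    ux <- ex / el; uy <- ey / el
    Fx <- P[ch$cid] * gy / 2 + tshare * ux - tshare[prv] * ux[prv]
    Fy <- P[ch$cid] * (-gx) / 2 + tshare * uy - tshare[prv] * uy[prv]
    # boundary integral with linear interpolation over each edge (i -> next)
    nxt <- ch$nxt
    Fxn <- Fx[nxt]; Fyn <- Fy[nxt]
    rxn <- rx[nxt]; ryn <- ry[nxt]
    ixx <- (Fx * rx + Fxn * rxn) / 3 + (Fx * rxn + Fxn * rx) / 6
    iyy <- (Fy * ry + Fyn * ryn) / 3 + (Fy * ryn + Fyn * ry) / 6
    ixy <- (Fx * ry + Fxn * ryn) / 3 + (Fx * ryn + Fxn * ry) / 6
    iyx <- (Fy * rx + Fyn * rxn) / 3 + (Fy * rxn + Fyn * rx) / 6
    # sign such that tension is positive (tensile) and a compressed cell has a
    # negative trace, matching the edge-dyad representation
    sxx <- -as.vector(rowsum(ixx, ch$cid)) / A
    syy <- -as.vector(rowsum(iyy, ch$cid)) / A
    sxy <- -(as.vector(rowsum(ixy, ch$cid)) +
               as.vector(rowsum(iyx, ch$cid))) / (2 * A)
  }
  mean2 <- (sxx + syy) / 2
  r <- sqrt(((sxx - syy) / 2)^2 + sxy^2)
  data.frame(cell = seq_along(A), sxx = sxx, sxy = sxy, syy = syy,
             sigma1 = mean2 + r, sigma2 = mean2 - r,
             magnitude = sxx + syy, anisotropy = 2 * r,
             orientation = (atan2(2 * sxy, sxx - syy) / 2) %% pi,
             boundary = ch$boundary_cell)
}

#' Single-cell stress tensor
#'
#' 2 x 2 stress tensor of one cell; see \code{\link{cell_stress}} for the two
#' representations.
#'
#' @param tissue a tissue object.
#' @param ci cell index.
#' @inheritParams cell_stress
#' @return a 2 x 2 symmetric matrix.
#' @export
stress_tensor <- function(tissue, ci, config = sim_config(),
                          method = c("B", "A")) {
  s <- cell_stress(tissue, config, method)[ci, ]
  matrix(c(s$sxx, s$sxy, s$sxy, s$syy), 2, 2)
}

#' Principal decomposition of a symmetric 2 x 2 tensor
#'
#' @param tensor symmetric 2 x 2 matrix.
#' @return list with \code{sigma1 >= sigma2}, \code{magnitude}
#'   (\code{sigma1+sigma2}), \code{anisotropy} (\code{sigma1-sigma2}),
#'   \code{orientation} of the maximum principal direction in [0, pi) and
#'   \code{degenerate} (TRUE for an isotropic tensor, whose orientation is
#'   reported as 0).
#' @export
principal_decomposition <- function(tensor) {
  stopifnot(all(dim(tensor) == 2), abs(tensor[1, 2] - tensor[2, 1]) < 1e-9)
  a <- tensor[1, 1]; b <- tensor[1, 2]; c <- tensor[2, 2]
  m <- (a + c) / 2
  r <- sqrt(((a - c) / 2)^2 + b^2)
  degen <- r < 1e-12 * max(abs(m), 1)
  list(sigma1 = m + r, sigma2 = m - r, magnitude = a + c, anisotropy = 2 * r,
       orientation = if (degen) 0 else (atan2(2 * b, a - c) / 2) %% pi,
       degenerate = degen)
}

#' Per-cell geometry table and heterogeneity summaries
#'
#' @param tissue a tissue object.
#' @return list with \code{cells} (data frame: area, inverse-area density,
#'   shape anisotropy, long-axis angle, boundary flag) and \code{summary}
#'   (CV of cell size, variance of cell size, mean anisotropy over interior
#'   cells).
#' @export
geometry_stats <- function(tissue) {
  a <- cell_areas(tissue)
  sh <- cell_shape(tissue)
  ch <- cache_of(tissue)
  cells <- data.frame(cell = seq_along(a), area = a, density = 1 / a,
                      anisotropy = sh$anisotropy,
                      long_angle = sh$long_angle,
                      boundary = ch$boundary_cell)
  int <- !cells$boundary
  use <- if (sum(int) >= 3) int else rep(TRUE, length(a))
  list(cells = cells,
       summary = list(cv_size = stats::sd(a[use]) / mean(a[use]),
                      var_size = stats::var(a[use]),
                      mean_anisotropy = mean(sh$anisotropy[use])))
}

## Fisher-Lee circular correlation via trigonometric moments (O(n))
circ_corr <- function(a, b) {
  s <- sin(a); c <- cos(a); S <- sin(b); C <- cos(b)
  num <- sum(s * S) * sum(c * C) - sum(s * C) * sum(c * S)
  d1 <- sum(s^2) * sum(c^2) - sum(s * c)^2
  d2 <- sum(S^2) * sum(C^2) - sum(S * C)^2
  num / sqrt(d1 * d2)
}

#' Stress-geometry correlations
#'
#' Pearson correlation of per-cell stress magnitude against cell area, of
#' stress anisotropy against shape anisotropy, and the circular correlation
#' (on doubled angles, since orientations have period pi) of the maximum
#' principal stress direction against the shape long-axis direction. Boundary
#' cells are excluded.
#'
#' @param tissue a tissue object (>= 100 interior cells).
#' @param config a \code{\link{sim_config}}.
#' @param method stress representation, \code{"B"} or \code{"A"}.
#' @param min_cells interior-cell requirement.
#' @return named numeric vector \code{rho_mag_area},
#'   \code{rho_aniso_aniso}, \code{rho_dir_dir}.
#' @export
stress_geometry_correlations <- function(tissue, config = sim_config(),
                                         method = c("B", "A"),
                                         min_cells = 100) {
  method <- match.arg(method)
  s <- cell_stress(tissue, config, method)
  g <- geometry_stats(tissue)$cells
  int <- !s$boundary & is.finite(s$magnitude)
  if (sum(int) < min_cells)
    stop(sprintf("need at least %d interior cells, have %d",
                 min_cells, sum(int)))
  c(rho_mag_area = stats::cor(s$magnitude[int], g$area[int]),
    rho_aniso_aniso = stats::cor(s$anisotropy[int], g$anisotropy[int]),
    rho_dir_dir = circ_corr(2 * s$orientation[int], 2 * g$long_angle[int]))
}

#' Mean local stress change around events
#'
#' Average change (after minus before, both post-relaxation) of the mean
#' stress magnitude over the ring-1 topological neighbourhood of each event
#' cell, separately for divisions and eliminations. Requires a run executed
#' with \code{track_stress = TRUE}.
#'
#' @param run a \code{\link{run_growth}} result.
#' @param kind \code{"division"} or \code{"t2"}.
#' @param ring neighbourhood radius; only ring 1 (adjacent cells) is
#'   supported, and 0 is an error (a neighbourhood is required).
#' @return list with per-event changes (\code{delta}) and their \code{mean}.
#' @export
local_stress_change <- function(run, kind = c("division", "t2"), ring = 1) {
  kind <- match.arg(kind)
  if (ring < 1) stop("ring must be >= 1: the change is measured on a neighbourhood")
  if (ring != 1) stop("only ring = 1 neighbourhoods are tracked")
  ev <- run$events
  d <- ev$ds_local[ev$kind == kind & !is.na(ev$ds_local)]
  list(delta = d, mean = if (length(d)) mean(d) else NA_real_,
       n = length(d))
}

#' Local density-heterogeneity change around eliminations
#'
#' Coefficient of variation of the inverse cell area (local density) over the
#' neighbourhood of each elimination, just before (including the eliminated
#' cell) and just after the event; both post-relaxation.
#'
#' @param run a \code{\link{run_growth}} result.
#' @param ring neighbourhood radius (ring 1 tracked; 0 is an error).
#' @return data frame with one row per usable elimination: \code{cv_before},
#'   \code{cv_after}.
#' @export
local_density_cv_change <- function(run, ring = 1) {
  if (ring < 1) stop("ring must be >= 1: the change is measured on a neighbourhood")
  if (ring != 1) stop("only ring = 1 neighbourhoods are tracked")
  ev <- run$events
  i <- ev$kind == "t2" & !is.na(ev$cv_before) & !is.na(ev$cv_after)
  data.frame(cv_before = ev$cv_before[i], cv_after = ev$cv_after[i])
}

#' Moran's I spatial autocorrelation on the cell-adjacency graph
#'
#' Standard Moran's I with binary (unnormalised) weights: 1 when two cells
#' share an edge.
#'
#' @param tissue a tissue object (or an adjacency list, one integer vector of
#'   neighbours per cell).
#' @param values numeric vector, one value per cell.
#' @return scalar Moran's I; \code{NA} with attribute \code{degenerate = TRUE}
#'   for constant input.
#' @export
morans_I <- function(tissue, values) {
  adj <- if (inherits(tissue, "tissue")) cell_adjacency(tissue) else tissue
  n <- length(adj)
  stopifnot(length(values) == n)
  z <- values - mean(values)
  if (sum(z^2) < 1e-300) {
    out <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  num <- 0; W <- 0
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    if (is.null(nb) || !length(nb)) next
    num <- num + z[i] * sum(z[nb])
    W <- W + length(nb)
  }
  (n / W) * num / sum(z^2)
}

#' Regional (center-to-periphery) statistics
#'
#' Splits the tissue into three concentric regions holding equal numbers of
#' cells (terciles of centroid distance from the tissue centroid) and reports
#' temporal averages over the run's snapshots: cell density (mean inverse
#' area), CV of cell size, elimination rate (eliminations per division) and
#' T1 count per division.
#'
#' @param run a \code{\link{run_growth}} result with snapshots.
#' @return data frame with one row per region (1 = center).
#' @export
regional_stats <- function(run) {
  snaps <- run$snapshots
  if (!length(snaps)) stop("run has no snapshots")
  acc <- matrix(0, 3, 2, dimnames = list(NULL, c("density", "cv_size")))
  nsnap <- 0
  for (sn in snaps) {
    tis <- sn$tissue
    cen <- cell_centroids(tis)
    mid <- colMeans(cen)
    rr <- sqrt((cen[, 1] - mid[1])^2 + (cen[, 2] - mid[2])^2)
    int <- !cache_of(tis)$boundary_cell   # rim cells excluded from statistics
    reg <- rep(NA_integer_, length(rr))
    reg[int] <- cut(rank(rr[int], ties.method = "first"), 3, labels = FALSE)
    a <- cell_areas(tis)
    for (k in 1:3) {
      sel <- !is.na(reg) & reg == k
      acc[k, "density"] <- acc[k, "density"] + mean(1 / a[sel])
      acc[k, "cv_size"] <- acc[k, "cv_size"] +
        stats::sd(a[sel]) / mean(a[sel])
    }
    nsnap <- nsnap + 1
  }
  acc <- acc / nsnap
  # assign events to regions by relative radius at the closest snapshot
  ev <- run$events
  counts <- matrix(0, 3, 3, dimnames = list(NULL, c("division", "t2", "t1")))
  snap_times <- vapply(snaps, `[[`, 0, "time")
  for (r in seq_len(nrow(ev))) {
    sn <- snaps[[which.min(abs(snap_times - ev$time[r]))]]
    cen <- cell_centroids(sn$tissue)
    mid <- colMeans(cen)
    rr <- sqrt((cen[, 1] - mid[1])^2 + (cen[, 2] - mid[2])^2)
    cuts <- stats::quantile(rr, c(1, 2) / 3)
    evr <- sqrt((ev$x[r] - mid[1])^2 + (ev$y[r] - mid[2])^2)
    k <- 1 + sum(evr > cuts)
    kind <- ev$kind[r]
    if (kind %in% colnames(counts)) counts[k, kind] <- counts[k, kind] + 1
  }
  data.frame(region = 1:3, density = acc[, "density"],
             cv_size = acc[, "cv_size"],
             eps = ifelse(counts[, "division"] > 0,
                          counts[, "t2"] / counts[, "division"], NA),
             t1_per_division = ifelse(counts[, "division"] > 0,
                                      counts[, "t1"] / counts[, "division"],
                                      NA))
}
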
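# Small meshes built in code, shared across test files.

# two unit squares sharing one edge (7 unit edges)
two_square_tissue <- function(config = sim_config(boundary_tension_mult = 1)) {
  pos <- rbind(c(0, 0), c(1, 0), c(2, 0), c(2, 1), c(1, 1), c(0, 1))
  new_tissue(pos, list(c(1L, 2L, 5L, 6L), c(2L, 3L, 4L, 5L)), config = config)
}

# regular hexagon of the given area, centred at the origin
single_hexagon_tissue <- function(area = 1, config = sim_config()) {
  s <- sqrt(2 * area / (3 * sqrt(3)))
  ang <- pi / 6 + (0:5) * pi / 3
  new_tissue(cbind(s * cos(ang), s * sin(ang)), list(1:6), config = config)
}

# regular hexagonal lattice patch with shared vertices, edge length l0
hex_lattice_tissue <- function(nx = 6, ny = 6, l0 = 0.62,
                               config = sim_config()) {
  width <- sqrt(3) * l0
  pos <- matrix(0, 0, 2)
  key <- character(0)
  cells <- list()
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      cx <- (i + (j %% 2) / 2) * width
      cy <- j * 1.5 * l0
      ang <- pi / 2 + (0:5) * pi / 3
      vxy <- cbind(cx + l0 * cos(ang), cy + l0 * sin(ang))
      ks <- sprintf("%.6f_%.6f", round(vxy[, 1], 6), round(vxy[, 2], 6))
      idx <- match(ks, key)
      for (v in which(is.na(idx))) {
        key <- c(key, ks[v])
        pos <- rbind(pos, vxy[v, ])
        idx[v] <- length(key)
      }
      cells[[length(cells) + 1L]] <- as.integer(idx)
    }
  }
  new_tissue(pos, cells, config = config)
}

# canonical 4-cell cross around a short central edge: two hexagons (left and
# right of the edge) and two pentagons (above and below); the central edge has
# the given length
four_cell_cross <- function(edge_len = 0.05, config = sim_config()) {
  a <- c(0, edge_len / 2)
  b <- c(0, -edge_len / 2)
  # ring of outer vertices
  TL <- c(-0.6, 0.9); TR <- c(0.6, 0.9)
  L1 <- c(-1.0, 0.35); L2 <- c(-1.0, -0.35)
  R1 <- c(1.0, 0.35); R2 <- c(1.0, -0.35)
  BL <- c(-0.6, -0.9); BR <- c(0.6, -0.9)
  pos <- rbind(a, b, TL, TR, L1, L2, R1, R2, BL, BR)
  # indices: a=1 b=2 TL=3 TR=4 L1=5 L2=6 R1=7 R2=8 BL=9 BR=10
  cells <- list(
    c(1L, 3L, 5L, 6L, 9L, 2L),   # left cell (contains edge b->a on its right)
    c(2L, 10L, 8L, 7L, 4L, 1L),  # right cell
    c(1L, 4L, 3L),               # top cell (triangle-ish, meets a)
    c(2L, 9L, 10L)               # bottom cell
  )
  tis <- new_tissue(pos, cells, config = config)
  validate_tissue(tis)
  tis
}

# root of the scalar equilibrium condition for an infinite hexagonal lattice:
# per-cell energy e(l) = (A(l)-1)^2/2 + 3*Lam*l + 18*Gam*l^2, A = 3*sqrt(3)/2 l^2
hex_equilibrium_length <- function(lam, gam) {
  c2 <- 3 * sqrt(3) / 2
  dU <- function(l) (c2 * l^2 - 1) * 2 * c2 * l + 3 * lam + 36 * gam * l
  # two stationary points exist; the stable minimum is the larger root
  stats::uniroot(dU, c(0.3, 0.7), tol = 1e-12)$root
}

# finite-difference gradient of the energy (oracle for compute_forces)
fd_forces <- function(tissue, config, h = 1e-6) {
  fd <- matrix(0, nrow(tissue$pos), 2)
  for (i in seq_len(nrow(tissue$pos))) {
    for (d in 1:2) {
      tp <- tissue; tp$pos[i, d] <- tp$pos[i, d] + h
      attr(tp, "cache") <- NULL
      tm <- tissue; tm$pos[i, d] <- tm$pos[i, d] - h
      attr(tm, "cache") <- NULL
      fd[i, d] <- -(compute_energy(tp, config) - compute_energy(tm, config)) /
        (2 * h)
    }
  }
  fd
}
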
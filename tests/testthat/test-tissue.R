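test_that("energy reproduces the hand-summed two-square case and its scalings", {
  cfg <- sim_config(lam0 = 0.14, gam0 = 0.04, boundary_tension_mult = 1)
  tis <- two_square_tissue(cfg)
  # areas 1 -> no area term; 7 unit edges at Lambda; two perimeters of 4
  expect_equal(compute_energy(tis, cfg), 0 + 7 * 0.14 + 2 * (0.04 / 2) * 16,
               tolerance = 1e-12)
  # all terms vanish at Lambda = Gamma = 0 and natural areas
  cfg0 <- sim_config(lam0 = 0, gam0 = 0, boundary_tension_mult = 1)
  expect_equal(compute_energy(two_square_tissue(cfg0), cfg0), 0)
  # doubling Gamma doubles only the perimeter term
  cfg2 <- sim_config(lam0 = 0.14, gam0 = 0.08, boundary_tension_mult = 1)
  tis2 <- two_square_tissue(cfg2)
  expect_equal(compute_energy(tis2, cfg2) - compute_energy(tis, cfg),
               2 * (0.04 / 2) * 16, tolerance = 1e-12)
})

test_that("analytic forces match finite-difference gradients", {
  # deformed irregular tissue so that every energy term is active
  cfg <- sim_config()
  tis <- generate_initial_tissue(24, seed = 3, config = cfg)
  tis$pos <- tis$pos * 0.85          # compress: area term nonzero
  set.seed(9)
  tis$pos <- tis$pos + matrix(stats::rnorm(length(tis$pos), sd = 0.01),
                              ncol = 2)
  attr(tis, "cache") <- NULL
  f <- compute_forces(tis, cfg)
  fd <- fd_forces(tis, cfg)
  expect_lt(max(abs(f - fd)) / max(abs(fd)), 1e-6)
  # mixed per-cell parameters exercise the effective-tension rule
  tis$state$lam <- seq(0.08, 0.2, length.out = length(tis$cells))
  f <- compute_forces(tis, cfg)
  fd <- fd_forces(tis, cfg)
  expect_lt(max(abs(f - fd)) / max(abs(fd)), 1e-6)
})

test_that("interior vertices of a hexagonal lattice are force-free at the scalar equilibrium", {
  cfg <- sim_config(boundary_tension_mult = 1)
  lstar <- hex_equilibrium_length(cfg$lam0, cfg$gam0)
  tis <- hex_lattice_tissue(6, 6, l0 = lstar, config = cfg)
  f <- compute_forces(tis, cfg)
  ch <- mcevertex:::build_cache(tis)
  # vertices whose incident cells are all interior
  interior_cells <- which(!ch$boundary_cell)
  vc <- split(ch$cid, ch$cv)
  deep <- as.integer(names(vc))[vapply(vc, function(cc)
    length(cc) == 3 && all(cc %in% interior_cells), TRUE)]
  expect_gt(length(deep), 0)
  expect_lt(max(abs(f[deep, ])), 1e-8)
})

test_that("translation invariance of energy and forces", {
  cfg <- sim_config()
  tis <- generate_initial_tissue(24, seed = 5, config = cfg)
  u0 <- compute_energy(tis, cfg)
  f0 <- compute_forces(tis, cfg)
  tis$pos <- sweep(tis$pos, 2, c(3.7, -1.2), "+")
  attr(tis, "cache") <- NULL
  expect_equal(compute_energy(tis, cfg), u0, tolerance = 1e-10)
  expect_equal(compute_forces(tis, cfg), f0, tolerance = 1e-8)
})

test_that("step is the identity at dt = 0 and in zero-force configurations", {
  cfg <- sim_config(lam0 = 0, gam0 = 0, boundary_tension_mult = 1)
  tis <- two_square_tissue(cfg)    # areas exactly 1, no tension: zero force
  expect_equal(max(abs(compute_forces(tis, cfg))), 0)
  expect_equal(step_vertices(tis, cfg, dt = cfg$dt)$pos, tis$pos)
  cfg2 <- sim_config()
  tis2 <- two_square_tissue(cfg2)
  expect_equal(step_vertices(tis2, cfg2, dt = 0)$pos, tis2$pos)
})

test_that("relax decreases energy and drives a perturbed lattice back toward equilibrium", {
  cfg <- sim_config(boundary_tension_mult = 1)
  lstar <- hex_equilibrium_length(cfg$lam0, cfg$gam0)
  tis <- hex_lattice_tissue(5, 5, l0 = lstar, config = cfg)
  set.seed(4)
  tis$pos <- tis$pos + matrix(stats::rnorm(length(tis$pos), sd = 0.02 * lstar),
                              ncol = 2)
  attr(tis, "cache") <- NULL
  u0 <- compute_energy(tis, cfg)
  energies <- u0
  for (k in 1:10) {
    tis <- relax(tis, cfg, force_tol = 1e-9, max_steps = 10)
    energies <- c(energies, compute_energy(tis, cfg))
  }
  expect_true(all(diff(energies) <= 1e-12))
  # once relaxed to tolerance, a repeat call returns after zero iterations
  tis <- relax(tis, cfg, force_tol = 1e-3, max_steps = 5000)
  expect_true(attr(tis, "converged"))
  again <- relax(tis, cfg, force_tol = 1e-3, max_steps = 5000)
  expect_identical(attr(again, "steps"), 0L)
  expect_true(attr(again, "converged"))
})

test_that("effective line tension follows the max / mean rules", {
  expect_equal(effective_line_tension(0.14, 0.20, "max"), 0.20)
  expect_equal(effective_line_tension(0.14, 0.14, "mean"), 0.14)
  # mean-field check: 3 white + 3 gray contacts under the mean rule
  lw <- 0.1; lg <- 0.2
  expect_equal(mean(effective_line_tension(rep(lw, 6), c(rep(lw, 3), rep(lg, 3)),
                                           "mean")),
               (3 * lw + 3 * ((lw + lg) / 2)) / 6)
  expect_error(effective_line_tension(-0.1, 0.2), "non-negative")
})

test_that("mesh invariants are enforced", {
  cfg <- sim_config()
  # clockwise square -> negative signed area
  bad <- new_tissue(rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0)),
                    list(c(1L, 2L, 3L, 4L)), config = cfg)
  expect_error(validate_tissue(bad), "orientation")
  # an edge in three cells
  pos <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(2, 0), c(2, 1))
  tri <- new_tissue(pos, list(c(1L, 2L, 3L, 4L), c(2L, 5L, 6L, 3L),
                              c(2L, 5L, 3L)), config = cfg)
  expect_error(validate_tissue(tri), "more than two")
  # degenerate (zero-area) cell is rejected by the energy
  sq <- new_tissue(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5)),
                   list(c(1L, 2L, 3L, 4L)), config = cfg)
  sq$cells[[1]] <- c(1L, 2L, 1L, 2L)
  expect_error(compute_energy(sq, cfg))
})
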
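test_that("shortest axis and shape anisotropy from the vertex second moments", {
  # axis-aligned 2x1 rectangle: short side along y, anisotropy 1 - 1/2
  rect <- rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1))
  ax <- shortest_axis(rect)
  expect_equal(ax$angle, pi / 2, tolerance = 1e-12)
  expect_equal(ax$anisotropy, 0.5, tolerance = 1e-12)
  # regular hexagon: circular second moment
  hexa <- single_hexagon_tissue()
  ax <- shortest_axis(hexa$pos[hexa$cells[[1]], ])
  expect_true(ax$degenerate)
  expect_equal(ax$anisotropy, 0)
  # sheared polygon: axes agree with PCA of densely sampled boundary points
  set.seed(1)
  ang <- sort(stats::runif(8, 0, 2 * pi))
  poly <- cbind(cos(ang), sin(ang))
  shear <- matrix(c(1, 0.8, 0, 1), 2, 2)
  poly <- poly %*% shear
  ax <- shortest_axis(poly)
  # oracle: dense sampling of the boundary segments, PCA long axis
  k <- nrow(poly); j <- c(2:k, 1)
  lam <- seq(0, 1, length.out = 60)[-60]
  bx <- as.vector(outer(1 - lam, poly[, 1]) + outer(lam, poly[j, 1]))
  by <- as.vector(outer(1 - lam, poly[, 2]) + outer(lam, poly[j, 2]))
  ev <- eigen(stats::cov(cbind(bx, by)))$vectors[, 1]
  long_oracle <- atan2(ev[2], ev[1]) %% pi
  d <- abs(ax$long_angle - long_oracle)
  expect_lt(min(d, pi - d), 5 * pi / 180)
})

test_that("von Mises division-axis sampling has the right concentration behaviour", {
  set.seed(42)
  # kappa = 0: uniform deviation on the axis period, near-maximal circular variance
  rect <- rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1))
  a0 <- replicate(400, sample_division_axis(rect, kappa = 0))
  dev2 <- 2 * (a0 - pi / 2)   # doubled deviation from the shortest axis
  R <- sqrt(mean(cos(dev2))^2 + mean(sin(dev2))^2)
  expect_lt(R, 0.15)
  # kappa = 100: 95% of deviations within +/- 8 degrees
  a1 <- replicate(400, sample_division_axis(rect, kappa = 100))
  dev <- abs((a1 - pi / 2 + pi / 2) %% pi - pi / 2)
  expect_gt(mean(dev < 8 * pi / 180), 0.95)
  # concentration limit: kappa -> large pins the axis
  a2 <- replicate(50, sample_division_axis(rect, kappa = 1e6))
  expect_lt(max(abs(a2 - pi / 2)), 0.01)
})

test_that("division splits a square into two half-area daughters and conserves geometry", {
  cfg <- sim_config(boundary_tension_mult = 1)
  sq <- new_tissue(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                   list(c(1L, 2L, 3L, 4L)), config = cfg)
  set.seed(1)
  out <- divide_cell(sq, 1L, pi / 2, cfg)
  ev <- attr(out, "event")
  expect_false(is.null(ev))
  expect_length(out$cells, 2)
  a <- cell_areas(out)
  expect_equal(unname(a), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(sum(a), 1, tolerance = 1e-12)
  # daughter cycle lengths sum to parent's + 4
  expect_equal(sum(lengths(out$cells)), 4 + 4)
  expect_equal(ev$d1 + 0L, 2L)  # fresh ids after the single parent
  validate_tissue(out, check_simple = TRUE)
})

test_that("division bookkeeping holds on irregular cells and neighbours gain a vertex", {
  cfg <- sim_config()
  set.seed(8)
  tis <- generate_initial_tissue(24, seed = 8, config = cfg)
  for (rep in 1:10) {
    ci <- sample(length(tis$cells), 1)
    k_parent <- length(tis$cells[[ci]])
    xy <- tis$pos[tis$cells[[ci]], , drop = FALSE]
    area_before <- sum(cell_areas(tis))
    n_before <- length(tis$cells)
    out <- divide_cell(tis, ci, sample_division_axis(xy, 0), cfg)
    if (is.null(attr(out, "event"))) next
    expect_length(out$cells, n_before + 1)
    # the two daughters share the two new vertices
    d1 <- out$cells[[ci]]; d2 <- out$cells[[length(out$cells)]]
    expect_equal(length(intersect(d1, d2)), 2)
    expect_equal(length(d1) + length(d2), k_parent + 4)
    expect_equal(sum(cell_areas(out)), area_before, tolerance = 1e-9)
    validate_tissue(out)
    tis <- out
  }
})

test_that("T1 reconnects the canonical four-cell cross and preserves cell count", {
  cfg <- sim_config(theta_T1 = 0.1)
  tis <- four_cell_cross(edge_len = 0.05, config = cfg)
  adj_before <- mcevertex:::cell_adjacency(tis)
  expect_true(2L %in% adj_before[[1]])      # left-right neighbours via the edge
  out <- apply_T1(tis, cfg)
  expect_identical(attr(out, "n_t1"), 1L)
  expect_length(out$cells, 4)
  validate_tissue(out, check_simple = TRUE)
  adj <- mcevertex:::cell_adjacency(out)
  expect_false(2L %in% adj[[1]])            # cells 1,2 separated,
  expect_true(4L %in% adj[[3]])             # cells 3,4 now neighbours
  # new edge has the expanded length
  ch <- mcevertex:::build_cache(out)
  p <- out$pos
  el <- sqrt((p[ch$v2, 1] - p[ch$cv, 1])^2 + (p[ch$v2, 2] - p[ch$cv, 2])^2)
  shared <- !ch$boundary_he & (ch$cid == 3 | ch$cid == 4) &
    (ch$partner_cell == 3 | ch$partner_cell == 4)
  expect_equal(unique(round(el[shared], 12)),
               round(cfg$t1_expansion * cfg$theta_T1, 12))
  # long-edge tissue is untouched
  calm <- four_cell_cross(edge_len = 0.5, config = cfg)
  out2 <- apply_T1(calm, cfg)
  expect_identical(attr(out2, "n_t1"), 0L)
  expect_equal(out2$cells, calm$cells)
})

test_that("T2 removes only sub-threshold cells and collapses them to a point", {
  cfg <- sim_config(theta_T2 = 0.2)
  # all areas comfortably above threshold: nothing happens
  tis <- generate_initial_tissue(24, seed = 2, config = cfg)
  expect_gt(min(cell_areas(tis)), 0.25)
  out <- apply_T2(tis, cfg)
  expect_length(attr(out, "t2_events"), 0)
  expect_length(out$cells, 24)
  # shrink one interior cell below threshold
  ch <- mcevertex:::build_cache(tis)
  ci <- which(!ch$boundary_cell)[1]
  v <- tis$cells[[ci]]
  cen <- colMeans(tis$pos[v, ])
  shrink <- tis
  a0 <- cell_areas(tis)[ci]
  s <- sqrt(0.19 / a0)
  shrink$pos[v, ] <- sweep(sweep(shrink$pos[v, ], 2, cen, "-") * s, 2, cen, "+")
  attr(shrink, "cache") <- NULL
  out <- apply_T2(shrink, cfg)
  evs <- attr(out, "t2_events")
  expect_length(evs, 1)
  expect_equal(evs[[1]]$area, 0.19, tolerance = 1e-9)
  expect_length(out$cells, 23)
  validate_tissue(out)
})

test_that("rosette vertices are resolved into three-fold junctions", {
  # 2 x 2 block of unit squares: the central vertex has four incident cells
  cfg <- sim_config(boundary_tension_mult = 1)
  pos <- as.matrix(expand.grid(x = 0:2, y = 0:2))[, 1:2]
  id <- function(x, y) x + 1L + 3L * y
  sq <- function(x, y) c(id(x, y), id(x + 1, y), id(x + 1, y + 1), id(x, y + 1))
  tis <- new_tissue(pos, list(sq(0, 0), sq(1, 0), sq(1, 1), sq(0, 1)),
                    config = cfg)
  validate_tissue(tis)
  out <- resolve_rosettes(tis, cfg)
  expect_identical(attr(out, "n_resolved"), 1L)
  validate_tissue(out, check_simple = TRUE)
  ch <- mcevertex:::build_cache(out)
  deg <- table(ch$cv)
  inner <- !ch$boundary_vertex[as.integer(names(deg))]
  expect_true(all(deg[inner] <= 3))
  # total area unchanged up to the small opening of the new edge
  expect_equal(sum(cell_areas(out)), 4, tolerance = 0.02)
})

test_that("clocks, gating and mitosis entry behave as specified", {
  cfg <- sim_config(mitosis_mode = "instant")
  tis <- two_square_tissue(cfg)
  tis$state$cycle_len <- c(10, 20)
  tis$state$clock <- c(9, 5)
  # frozen clocks under a zero gate
  frozen <- advance_clocks(tis, dt = 5, gate = 0, config = cfg)
  expect_equal(frozen$state$clock, c(9, 5))
  # dt = T - tau triggers division in instant mode
  out <- advance_clocks(tis, dt = 1, gate = 1, config = cfg)
  expect_identical(attr(out, "divide_now"), 1L)
  # ramp mode raises the mitotic flag and snapshots the area instead
  cfg2 <- sim_config(mitosis_mode = "ramp")
  out2 <- advance_clocks(tis, dt = 1, gate = 1, config = cfg2)
  expect_identical(attr(out2, "divide_now"), integer(0))
  expect_true(out2$state$mitotic[1])
  expect_equal(out2$state$pre_mitotic_area[1], 1)
})

test_that("mitotic natural-area ramp doubles an isolated cell and then divides it", {
  cfg <- sim_config(lam0 = 0, gam0 = 0, boundary_tension_mult = 1,
                    relax_force_tol = 1e-9, relax_max_steps = 2000)
  hexa <- single_hexagon_tissue(config = cfg)
  hexa$state$mitotic <- TRUE
  hexa$state$pre_mitotic_area <- cell_areas(hexa)
  ramp_time <- cfg$mitosis_ramp_frac * cfg$cycle_len_mean
  t_el <- 0
  repeat {
    hexa <- mitotic_growth(hexa, dt = 1, config = cfg)
    hexa <- relax(hexa, cfg)
    t_el <- t_el + 1
    if (length(attr(hexa, "divide_now"))) break
    if (t_el > 3 * ramp_time) break
  }
  # with no tension terms the free cell tracks its natural area: doubling
  # takes about one ramp time
  expect_equal(cell_areas(hexa), 2, tolerance = 0.1)
  expect_lt(abs(t_el - ramp_time), 0.2 * ramp_time)
})

test_that("growth runs are deterministic and keep exact cell-count books", {
  # a soft rim keeps very small test tissues from evaporating
  cfg <- sim_config(seed = 21, init_n = 40, snapshot_every = 20,
                    boundary_tension_mult = 1)
  r1 <- run_growth(cfg, n_target = 60)
  r2 <- run_growth(cfg, n_target = 60)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$tissue$pos, r2$tissue$pos)
  n0 <- r1$g[1]      # settled pre-growth count
  nd <- sum(r1$events$kind == "division")
  ne <- sum(r1$events$kind == "t2")
  expect_identical(r1$g[length(r1$g)], n0 + nd - ne)
  # cell count at every recorded time equals initial + divisions - eliminations
  for (i in seq_along(r1$times)) {
    upto <- r1$events$time <= r1$times[i]
    expect_identical(r1$g[i],
                     n0 + sum(upto & r1$events$kind == "division") -
                       sum(upto & r1$events$kind == "t2"))
  }
  validate_tissue(r1$tissue)
})

test_that("a non-proliferating tissue stays static", {
  cfg <- sim_config(seed = 3, init_n = 24, mu = 0, boundary_tension_mult = 1)
  run <- run_growth(cfg, n_target = NULL, t_end = 10)
  expect_identical(unique(run$g), 24L)
  expect_identical(nrow(run$events[run$events$kind == "division", ]), 0L)
})
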
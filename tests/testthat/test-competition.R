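test_that("trait inheritance has the stated copy probability", {
  set.seed(1)
  expect_true(all(inherit_trait(rep(3L, 50), q = 1, N = 10) == 3L))
  u <- inherit_trait(rep(3L, 20000), q = 0, N = 10)
  expect_equal(as.vector(table(u)) / 20000, rep(0.1, 10), tolerance = 0.02)
  # q = 0.5, N = 10: P(parental) = 0.5 + 0.5/10 = 0.55
  v <- inherit_trait(rep(3L, 20000), q = 0.5, N = 10)
  expect_equal(mean(v == 3L), 0.55, tolerance = 0.015)
})

test_that("inheritance matrix has the stated structure and limits", {
  expect_equal(inheritance_matrix(1, 7), diag(7))
  expect_equal(inheritance_matrix(0, 5), matrix(1 / 5, 5, 5))
  for (q in c(0.2, 0.63, 0.9)) {
    Q <- inheritance_matrix(q, 9)
    expect_equal(colSums(Q), rep(1, 9))
    expect_equal(unique(diag(Q)), q + (1 - q) / 9)
    expect_equal(unique(Q[upper.tri(Q)]), (1 - q) / 9)
  }
})

test_that("heritability estimate matches the copying probability and is monotone in q", {
  grid <- seq(0.06, 0.26, length.out = 10)
  sim_pairs <- function(q, n = 4000) {
    parent <- sample.int(10, n, replace = TRUE)
    off <- inherit_trait(parent, q, 10)
    list(p = grid[parent], o = grid[off])
  }
  set.seed(5)
  pr <- sim_pairs(1)
  expect_equal(estimate_heritability(pr$p, pr$o)$h2, 1, tolerance = 1e-12)
  pr0 <- sim_pairs(0)
  expect_lt(abs(estimate_heritability(pr0$p, pr0$o)$h2), 0.05)
  h2s <- vapply(c(0, 0.3, 0.6, 0.9), function(q) {
    pr <- sim_pairs(q)
    estimate_heritability(pr$p, pr$o)$h2
  }, 0)
  expect_true(all(diff(h2s) > 0))
  expect_error(estimate_heritability(1:10, 1:10), "at least 100")
})

test_that("mean-field effective traits follow the max-rule formula", {
  # N = 2, grid (1, 2), uniform f: (1*0.5 + 2*0.5, 2)
  expect_equal(mean_field_effective_trait(c(0.5, 0.5), c(1, 2)), c(1.5, 2))
  # concentrated frequency: own value
  expect_equal(mean_field_effective_trait(c(0, 1, 0), c(1, 2, 3))[2], 2)
  # uniform limit equals (i L_i + sum_{k>i} L_k) / N
  grid <- seq(0.06, 0.26, length.out = 10)
  N <- length(grid)
  eff <- mean_field_effective_trait(rep(1 / N, N), grid)
  oracle <- vapply(seq_len(N), function(i)
    (i * grid[i] + sum(grid[seq_len(N) > i])) / N, 0)
  expect_equal(eff, oracle, tolerance = 1e-12)
  # effective tension never below the cell's own value
  set.seed(2)
  f <- stats::runif(N); f <- f / sum(f)
  expect_true(all(mean_field_effective_trait(f, grid) >= grid - 1e-12))
  expect_error(mean_field_effective_trait(f, rev(grid)), "ascending")
})

test_that("fitness from a calibrated response has the printed limits", {
  T <- log(2) / 3.47e-3
  expect_equal(fitness_from_eps_fn(0.5, function(z) 0, T), log(2) / T)
  expect_equal(fitness_from_eps_fn(0.5, function(z) 1, T), 0)
  fitref <- gaussian_response(245, 0.24, 0)
  expect_equal(fitness_from_eps_fn(0.14, fitref, T),
               log(2 - exp(-245 * 0.01)) / T, tolerance = 1e-12)
  expect_error(fitness_from_eps_fn(0.5, function(z) 2.5, T), "below 2")
})

test_that("closed-form competition equals brute-force integration of the constant system", {
  grid <- seq(0.06, 0.26, length.out = 8)
  eps_fn <- gaussian_response(245, 0.24, 0)
  T <- log(2) / 3.47e-3
  tg <- seq(0, 3000, by = 300)
  x0 <- rep(100, 8)
  cf <- solve_competition(x0, grid, q = 0.8, eps_fn, T, tg, mode = "closed_form")
  # oracle: dense RK integration of dx = Q Phi x with the same constant Phi
  Q <- inheritance_matrix(0.8, 8)
  phi <- log(2 - predict(eps_fn, grid)) / T
  M <- Q %*% diag(phi)
  oracle <- deSolve::ode(y = x0, times = tg,
                         func = function(t, y, p) list(as.vector(M %*% y)),
                         parms = NULL, method = "ode45",
                         rtol = 1e-10, atol = 1e-10)
  expect_equal(unname(cf$x), unname(oracle[, -1]), tolerance = 1e-8)
  # N = 1 scalar case
  one <- solve_competition(50, grid[3], q = 1, eps_fn, T, tg, "closed_form")
  expect_equal(as.vector(one$x),
               50 * exp(log(2 - predict(eps_fn, grid[3])) / T * tg),
               tolerance = 1e-8)
})

test_that("no inheritance keeps the trait distribution flat and fitness constant", {
  grid <- seq(0.06, 0.26, length.out = 10)
  eps_fn <- gaussian_response(245, 0.24, 0)
  T <- log(2) / 3.47e-3
  tg <- seq(0, 4000, by = 400)
  sol <- solve_competition(rep(10, 10), grid, q = 0, eps_fn, T, tg, "mean_field")
  expect_lt(max(abs(sweep(sol$f, 2, sol$f[1, ]))), 1e-6)
  expect_lt(diff(range(sol$phi_tissue)), 1e-8)
  # high heritability shifts frequency toward fluid (low-tension) traits and
  # raises tissue fitness
  sol1 <- solve_competition(rep(10, 10), grid, q = 1, eps_fn, T, tg, "mean_field")
  expect_lt(sum(sol1$f[length(tg), ] * grid), sum(sol1$f[1, ] * grid))
  expect_gt(sol1$phi_tissue[length(tg)], sol1$phi_tissue[1])
})

test_that("cumulative eliminations are monotone decreasing in heritability", {
  grid <- seq(0.06, 0.26, length.out = 10)
  eps_fn <- gaussian_response(245, 0.24, 0)
  T <- log(2) / 3.47e-3
  tg <- seq(0, 4000, by = 200)
  elim <- vapply(c(0, 0.3, 0.6, 0.9, 1), function(q) {
    sol <- solve_competition(rep(10, 10), grid, q, eps_fn, T, tg, "mean_field")
    # compare at a matched final population, not a matched time
    n_end <- sum(sol$x[length(tg), ])
    sol$eliminated[length(tg)] / n_end
  }, 0)
  expect_true(all(diff(elim) < 0))
})

test_that("the adhesion-proliferation tradeoff creates an interior optimum", {
  expect_equal(tradeoff_growth_rate(0), 0.5)
  expect_equal(tradeoff_growth_rate(1e3), 1)
  lam <- seq(0, 0.3, by = 0.05)
  expect_true(all(diff(tradeoff_growth_rate(lam)) > 0))
  grid <- seq(0.06, 0.26, length.out = 10)
  eps_fn <- gaussian_response(245, 0.24, 0)
  T <- log(2) / 3.47e-3
  tg <- seq(0, 30000, by = 1000)
  sol <- solve_competition(rep(10, 10), grid, q = 0.87, eps_fn, T, tg,
                           mode = "mean_field",
                           mu_fn = function(l)
                             tradeoff_growth_rate(l, base_rate = log(2) / T))
  fT <- sol$f[length(tg), ]
  peak <- which.max(fT)
  expect_gt(peak, 1)
  expect_lt(peak, 10)
})

test_that("uniform-limit mode matches mean field at q = 0", {
  grid <- seq(0.06, 0.26, length.out = 6)
  eps_fn <- gaussian_response(245, 0.24, 0)
  T <- 200
  tg <- seq(0, 2000, by = 200)
  mf <- solve_competition(rep(5, 6), grid, 0, eps_fn, T, tg, "mean_field")
  ul <- solve_competition(rep(5, 6), grid, 0, eps_fn, T, tg, "uniform_limit")
  expect_equal(unname(mf$x[length(tg), ]), unname(ul$x[length(tg), ]),
               tolerance = 1e-4)
})
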
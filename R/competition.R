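## Heritable traits, heritability, and the trait-frequency competition ODE.

#' Draw a daughter trait
#'
#' The daughter copies the parental trait with probability \code{q} and
#' otherwise draws uniformly among the N trait values, so
#' P(same as parent) = q + (1-q)/N.
#'
#' @param parent_trait parental trait index (vectorised).
#' @param q inheritance probability in [0, 1].
#' @param N number of traits.
#' @return daughter trait index (or indices).
#' @export
inherit_trait <- function(parent_trait, q, N) {
  stopifnot(q >= 0, q <= 1, N >= 1)
  n <- length(parent_trait)
  copy <- stats::runif(n) < q
  out <- parent_trait
  out[!copy] <- sample.int(N, sum(!copy), replace = TRUE)
  out
}

#' Inheritance matrix
#'
#' N x N matrix with diagonal \code{q + (1-q)/N} and off-diagonal
#' \code{(1-q)/N}; columns sum to 1. \code{q = 1} gives the identity,
#' \code{q = 0} uniform redistribution.
#'
#' @inheritParams inherit_trait
#' @return numeric matrix.
#' @export
inheritance_matrix <- function(q, N) {
  stopifnot(q >= 0, q <= 1, N >= 1)
  matrix((1 - q) / N, N, N) + diag(q, N)
}

#' Estimate heritability from parent-offspring pairs
#'
#' Heritability is reported as the slope of the offspring-on-parent trait
#' regression (the asexual-copying analogue of the parent-offspring
#' regression), with a bootstrap confidence interval.
#'
#' @param parent,offspring numeric trait values, pairs aligned (>= 100 pairs).
#' @param n_boot bootstrap replicates.
#' @param level confidence level.
#' @return list with \code{h2}, \code{ci} and the number of pairs.
#' @export
estimate_heritability <- function(parent, offspring, n_boot = 200,
                                  level = 0.95) {
  stopifnot(length(parent) == length(offspring))
  n <- length(parent)
  if (n < 100) stop("need at least 100 parent-offspring pairs")
  if (stats::var(parent) < 1e-12) stop("no parental trait variance")
  slope <- function(p, o) stats::cov(p, o) / stats::var(p)
  h2 <- slope(parent, offspring)
  bs <- vapply(seq_len(n_boot), function(i) {
    j <- sample.int(n, n, replace = TRUE)
    if (stats::var(parent[j]) < 1e-12) return(NA_real_)
    slope(parent[j], offspring[j])
  }, 0)
  ci <- stats::quantile(bs, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  list(h2 = h2, ci = ci, n = n)
}

#' Mean-field effective trait values
#'
#' Under the max rule the effective line tension a cell of trait i feels on a
#' random contact is \eqn{\tilde\Lambda_i = \Lambda_i \sum_{k \le i} f_k +
#' \sum_{k > i} \Lambda_k f_k} (the grid must be ascending). With a uniform
#' frequency vector this reduces to the constant
#' \eqn{(i \Lambda_i + \sum_{k>i} \Lambda_k)/N}.
#'
#' @param f trait frequencies (simplex).
#' @param trait_grid ascending trait values.
#' @return effective trait value per trait; never below the cell's own value.
#' @export
mean_field_effective_trait <- function(f, trait_grid) {
  if (is.unsorted(trait_grid)) stop("trait grid must be ascending")
  N <- length(trait_grid)
  stopifnot(length(f) == N)
  cs <- cumsum(f)
  tail_sum <- rev(cumsum(rev(trait_grid * f)))       # sum_{k >= i} L_k f_k
  tail_above <- c(tail_sum[-1], 0)                   # sum_{k > i} L_k f_k
  trait_grid * cs + tail_above
}

#' Cellular fitness from a calibrated elimination-rate response
#'
#' \eqn{\phi = \log(2 - \varepsilon(\tilde\Lambda)) / T}: each cycle a trait's
#' population multiplies by \eqn{2 - \varepsilon}.
#'
#' @param lam_eff effective trait value(s).
#' @param eps_fn a \code{\link{gaussian_response}} (or any function of the
#'   trait value returning an elimination rate in [0, 2)).
#' @param T cell-cycle time.
#' @return fitness value(s).
#' @export
fitness_from_eps_fn <- function(lam_eff, eps_fn, T) {
  eps <- if (inherits(eps_fn, "gaussian_response"))
    predict(eps_fn, lam_eff) else eps_fn(lam_eff)
  if (any(eps < 0)) eps <- pmax(eps, 0)
  if (any(eps >= 2)) stop("elimination rate must be below 2")
  log(2 - eps) / T
}

#' Adhesion-proliferation tradeoff
#'
#' Cells with lower line tension (stronger adhesion) proliferate more slowly:
#' the proliferation rate is scaled by the logistic factor
#' \eqn{1/(1+e^{-10\Lambda})}.
#'
#' @param lam line-tension value(s).
#' @param base_rate unscaled proliferation rate.
#' @return scaled rate(s).
#' @export
tradeoff_growth_rate <- function(lam, base_rate = 1) {
  base_rate / (1 + exp(-10 * lam))
}

#' Solve the trait-frequency competition dynamics
#'
#' Integrates \eqn{dx/dt = Q_q \Phi(t) x} for the per-trait cell counts, where
#' \eqn{Q_q} is the inheritance matrix and \eqn{\Phi} the diagonal matrix of
#' cellular fitnesses.
#'
#' Modes: \code{"closed_form"} treats \eqn{\Phi} as constant at the
#' pure-population fitness of each trait (valid for high heritability, where
#' descendants form clusters) and evaluates the matrix exponential
#' \eqn{x(t) = e^{Q_q \Phi t} x(0)}; \code{"mean_field"} recomputes the
#' effective trait of each cell type from the current frequencies (max rule)
#' at every step and integrates numerically (valid for low heritability,
#' where traits are well mixed); \code{"uniform_limit"} freezes the effective
#' traits at their uniform-frequency values and solves in closed form.
#'
#' The cumulative number of eliminated cells is accumulated alongside as
#' \eqn{\int \sum_i m_i(t) x_i(t) dt} with \eqn{m_i = -\log(1-\varepsilon_i/2)/T}.
#'
#' @param x0 initial per-trait counts.
#' @param trait_grid ascending trait values.
#' @param q inheritance probability.
#' @param eps_fn calibrated elimination-rate response (see
#'   \code{\link{fitness_from_eps_fn}}).
#' @param T cell-cycle time.
#' @param t_grid output times (starting at 0).
#' @param mode one of \code{"closed_form"}, \code{"mean_field"},
#'   \code{"uniform_limit"}.
#' @param mu_fn optional per-trait proliferation-rate function of the trait
#'   value (e.g. \code{\link{tradeoff_growth_rate}}); when supplied the
#'   fitness becomes \eqn{\mu(\Lambda)\,\log(2-\varepsilon)/\log 2}.
#' @return object of class \code{competition_ode}: \code{times}, \code{x}
#'   (counts), \code{f} (frequencies), \code{phi_tissue}, \code{eliminated}
#'   (cumulative), plus the inputs.
#' @export
solve_competition <- function(x0, trait_grid, q, eps_fn, T,
                              t_grid, mode = c("closed_form", "mean_field",
                                               "uniform_limit"),
                              mu_fn = NULL) {
  mode <- match.arg(mode)
  N <- length(trait_grid)
  stopifnot(length(x0) == N, all(x0 >= 0), !is.unsorted(trait_grid),
            t_grid[1] == 0)
  Q <- inheritance_matrix(q, N)
  eps_of <- function(lam_eff) {
    e <- if (inherits(eps_fn, "gaussian_response")) predict(eps_fn, lam_eff)
    else eps_fn(lam_eff)
    pmin(pmax(e, 0), 2 - 1e-12)
  }
  phi_of <- function(lam_eff) {
    if (is.null(mu_fn)) log(2 - eps_of(lam_eff)) / T
    else mu_fn(trait_grid) * log(2 - eps_of(lam_eff)) / log(2)
  }
  m_of <- function(lam_eff) {
    if (is.null(mu_fn)) -log(1 - eps_of(lam_eff) / 2) / T
    else -mu_fn(trait_grid) * log(1 - eps_of(lam_eff) / 2) / log(2)
  }
  if (mode == "mean_field") {
    ## integrate in normalised form (frequencies + log population size) so
    ## that long horizons with exponential growth stay well conditioned;
    ## w tracks eliminated cells per current cell
    deriv <- function(t, y, parms) {
      f <- y[seq_len(N)]
      f <- pmax(f, 0)
      f <- f / sum(f)
      lam_eff <- mean_field_effective_trait(f, trait_grid)
      growth <- as.vector(Q %*% (phi_of(lam_eff) * f))
      glog <- sum(growth)
      df <- growth - f * glog
      dw <- sum(m_of(lam_eff) * f) - y[N + 2] * glog
      list(c(df, glog, dw))
    }
    n0 <- sum(x0)
    sol <- deSolve::ode(y = c(x0 / n0, log(n0), 0), times = t_grid,
                        func = deriv, parms = NULL, method = "lsoda")
    f_traj <- sol[, 2:(N + 1), drop = FALSE]
    ntot <- exp(sol[, N + 2])
    x <- f_traj * ntot
    eliminated <- sol[, N + 3] * ntot
  } else {
    lam_eff <- if (mode == "closed_form") trait_grid
    else mean_field_effective_trait(rep(1 / N, N), trait_grid)
    M <- Q %*% diag(phi_of(lam_eff), N)
    x <- matrix(NA_real_, length(t_grid), N)
    x[1, ] <- x0
    for (i in seq_along(t_grid)[-1]) {
      E <- Matrix::expm(M * t_grid[i])
      x[i, ] <- as.vector(E %*% x0)
    }
    m <- m_of(lam_eff)
    loss_rate <- x %*% m
    eliminated <- c(0, cumsum((loss_rate[-1] + loss_rate[-length(t_grid)]) / 2 *
                                diff(t_grid)))
  }
  if (any(x < -1e-8)) stop("negative trait counts: integration failed")
  x <- pmax(x, 0)
  f <- x / rowSums(x)
  phi_tissue <- vapply(seq_along(t_grid), function(i) {
    lam_eff <- if (mode == "mean_field")
      mean_field_effective_trait(f[i, ], trait_grid)
    else if (mode == "closed_form") trait_grid
    else mean_field_effective_trait(rep(1 / N, N), trait_grid)
    sum(f[i, ] * phi_of(lam_eff))
  }, 0)
  out <- list(times = t_grid, x = x, f = f, phi_tissue = phi_tissue,
              eliminated = eliminated, trait_grid = trait_grid, q = q,
              mode = mode, T = T)
  class(out) <- "competition_ode"
  out
}

#' @export
print.competition_ode <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("competition dynamics (%s), q = %g, %d traits\n",
              x$mode, x$q, length(x$trait_grid)))
  cat(sprintf("  population %.3g -> %.3g; eliminated %.3g\n",
              sum(x$x[1, ]), sum(x$x[n, ]), x$eliminated[n]))
  cat(sprintf("  tissue fitness %.5g -> %.5g\n",
              x$phi_tissue[1], x$phi_tissue[n]))
  cat(sprintf("  modal trait %.4g -> %.4g\n",
              x$trait_grid[which.max(x$f[1, ])],
              x$trait_grid[which.max(x$f[n, ])]))
  invisible(x)
}

#' @export
plot.competition_ode <- function(x, ...) {
  n <- length(x$times)
  graphics::matplot(x$times, x$f, type = "l", lty = 1,
                    xlab = "time", ylab = "trait frequency", ...)
  invisible(x)
}
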
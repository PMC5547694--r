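## Elimination rate, mortality, cellular/tissue fitness, and the
## Gaussian-type fit of the elimination-rate response to a parameter.

#' Elimination rate per window of tissue growth
#'
#' The elimination rate is the number of eliminated cells per newly born cell,
#' \eqn{\varepsilon = N_{eliminated} / N_{produced}}, evaluated in windows of
#' fixed tissue-size increment; its temporal average is the typical value for
#' a parameter set.
#'
#' @param run a \code{\link{run_growth}} result (or a data frame of events
#'   with columns \code{time} and \code{kind}, in which case \code{times} and
#'   \code{g} must be given).
#' @param window_cells tissue-size increment per window.
#' @param times,g tissue-size series when \code{run} is an event table.
#' @param burn_in tissue-size increment excluded from the temporal mean: a
#'   freshly seeded tissue passes through a brief densification transient with
#'   elevated elimination, which the long growth ranges this average emulates
#'   would render negligible.
#' @return list with \code{windows} (data frame: size bounds, divisions,
#'   eliminations, eps) and \code{mean}, the temporal average over
#'   post-burn-in windows that contain at least one division.
#' @export
elimination_rate <- function(run, window_cells = 250, times = NULL, g = NULL,
                             burn_in = 0) {
  if (inherits(run, "growth_run")) {
    events <- run$events; times <- run$times; g <- run$g
  } else events <- run
  stopifnot(!is.null(times), !is.null(g), window_cells > 0)
  if (!nrow(events))
    return(list(windows = data.frame(size_lo = numeric(0),
                                     size_hi = numeric(0), n_div = integer(0),
                                     n_elim = integer(0), eps = numeric(0)),
                mean = NA_real_))
  size_at <- stats::approxfun(times, g, method = "constant", rule = 2)
  esz <- size_at(events$time)
  lo <- seq(min(g), max(g), by = window_cells)
  win <- findInterval(esz, lo)
  n_win <- max(win)
  n_div <- tabulate(win[events$kind == "division"], n_win)
  n_elim <- tabulate(win[events$kind == "t2"], n_win)
  windows <- data.frame(size_lo = lo[seq_len(n_win)],
                        size_hi = lo[seq_len(n_win)] + window_cells,
                        n_div = n_div, n_elim = n_elim,
                        eps = ifelse(n_div > 0, n_elim / n_div, NA))
  use <- n_div > 0 & windows$size_lo >= min(g) + burn_in
  if (!any(use)) use <- n_div > 0
  list(windows = windows, mean = mean(windows$eps[use]))
}

#' Mortality implied by an elimination rate
#'
#' With cycle time T, one division per cell per T and elimination rate
#' \eqn{\varepsilon} per produced cell, the population multiplies by
#' \eqn{(2-\varepsilon)} per cycle; matching an exponential decay channel
#' gives \eqn{m = -\log(1 - \varepsilon/2) / T}.
#'
#' @param eps elimination rate(s) in [0, 2).
#' @param T cell-cycle time (> 0).
#' @return mortality rate(s).
#' @export
mortality_from_eps <- function(eps, T) {
  if (any(eps < 0 | eps >= 2)) stop("eps must lie in [0, 2)")
  stopifnot(T > 0)
  -log(1 - eps / 2) / T
}

## smoothed d log g / dt on a (possibly irregular) series
log_derivative <- function(times, g, k = 7) {
  stopifnot(length(times) == length(g), all(g > 0))
  if (length(g) < 5) stop("too few samples for a fitness estimate")
  k <- min(k, length(g) - (length(g) + 1) %% 2)
  if (k %% 2 == 0) k <- k - 1
  gs <- if (k >= 3) stats::runmed(g, k) else g
  lg <- log(gs)
  n <- length(lg)
  phi <- rep(NA_real_, n)
  phi[2:(n - 1)] <- (lg[3:n] - lg[1:(n - 2)]) / (times[3:n] - times[1:(n - 2)])
  phi
}

#' Tissue fitness
#'
#' \eqn{\phi_{Tissue}(t) = d \log g(t) / dt}: the local exponent of the
#' tissue growth curve (median-filtered, centred differences). For a mixed
#' population the same object also carries the frequency-weighted
#' decomposition \eqn{\sum_i f_i \phi_{Cell,i}}, which is algebraically
#' identical to the direct derivative.
#'
#' @param run a \code{\link{run_growth}} result, or a numeric time vector.
#' @param g cell counts when \code{run} is a time vector.
#' @param k median-filter width.
#' @return data frame with \code{time}, \code{phi} and, when per-trait counts
#'   are available, \code{phi_decomposed}.
#' @export
tissue_fitness <- function(run, g = NULL, k = 7) {
  if (inherits(run, "growth_run")) {
    times <- run$times; g <- run$g; tc <- run$trait_counts
  } else {
    times <- run; tc <- NULL
  }
  out <- data.frame(time = times, phi = log_derivative(times, g, k))
  if (!is.null(tc)) {
    f <- tc / rowSums(tc)
    phic <- apply(tc, 2, function(gi) {
      gi_pos <- pmax(gi, 0.5)   # extinct traits contribute ~0 weight anyway
      log_derivative(times, gi_pos, k)
    })
    out$phi_decomposed <- rowSums(f * phic, na.rm = FALSE)
  }
  out
}

#' Cellular fitness of one trait
#'
#' \eqn{\phi_{Cell,i}(t) = d \log g_i(t) / dt} from the per-trait growth
#' curve; reported up to the extinction time when the trait dies out.
#'
#' @param run a \code{\link{run_growth}} result of a mixed population (or a
#'   time vector, with \code{gi} the trait's counts).
#' @param trait trait index.
#' @param gi counts when \code{run} is a time vector.
#' @param k median-filter width.
#' @return data frame with \code{time} and \code{phi}.
#' @export
cellular_fitness <- function(run, trait = 1, gi = NULL, k = 7) {
  if (inherits(run, "growth_run")) {
    if (is.null(run$trait_counts)) stop("run has no per-trait counts")
    times <- run$times
    gi <- run$trait_counts[, trait]
  } else times <- run
  alive <- gi > 0
  last <- if (all(alive)) length(gi) else which(!alive)[1] - 1L
  if (last < 5) stop("trait extinct too early for a fitness estimate")
  data.frame(time = times[seq_len(last)],
             phi = log_derivative(times[seq_len(last)], gi[seq_len(last)], k))
}

#' Fitness and frequency series of a run
#'
#' @param run a \code{\link{run_growth}} result.
#' @return data frame with time, cell count, tissue fitness, and per-trait
#'   frequencies for mixed populations.
#' @export
fitness_series <- function(run) {
  out <- tissue_fitness(run)
  out$g <- run$g
  if (!is.null(run$trait_counts)) {
    f <- run$trait_counts / rowSums(run$trait_counts)
    colnames(f) <- paste0("f", seq_len(ncol(f)))
    out <- cbind(out, f)
  }
  out
}

#' Gaussian-type fit of the elimination-rate response
#'
#' Fits \eqn{\varepsilon(\zeta) = \exp[-\alpha (\zeta - \beta)^2] + \gamma}
#' to a one-parameter sweep by nonlinear least squares with multiple starts
#' over the centre \eqn{\beta} (the response is unimodal but the loss surface
#' has local minima).
#'
#' @param zeta parameter values (>= 4 distinct points).
#' @param eps observed elimination rates.
#' @param n_starts number of starting centres spread over the data range.
#' @return object of class \code{gaussian_response} with \code{alpha},
#'   \code{beta}, \code{gamma}, \code{residual} (norm), and
#'   \code{degenerate} flag (constant data); supports \code{coef},
#'   \code{predict} and \code{print}.
#' @export
fit_gaussian_response <- function(zeta, eps, n_starts = 8) {
  ok <- is.finite(zeta) & is.finite(eps)
  zeta <- zeta[ok]; eps <- eps[ok]
  if (length(unique(zeta)) < 4) stop("need at least 4 distinct points")
  if (stats::sd(eps) < 1e-10) {
    out <- list(alpha = 0, beta = mean(zeta), gamma = mean(eps),
                residual = 0, degenerate = TRUE, param = NULL)
    class(out) <- "gaussian_response"
    return(out)
  }
  rng <- range(zeta)
  span <- diff(rng)
  betas <- seq(rng[1] - 0.25 * span, rng[2] + 0.5 * span,
               length.out = n_starts)
  best <- NULL
  for (b0 in betas) {
    a0 <- 1 / (0.3 * span)^2
    g0 <- max(min(eps), 0)
    fit <- tryCatch(
      minpack.lm::nlsLM(eps ~ exp(-alpha * (zeta - beta)^2) + gamma,
                        start = list(alpha = a0, beta = b0, gamma = g0),
                        lower = c(alpha = 0, beta = -Inf, gamma = -1),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("Gaussian response fit failed from all starts")
  cf <- stats::coef(best$fit)
  out <- list(alpha = unname(cf["alpha"]), beta = unname(cf["beta"]),
              gamma = unname(cf["gamma"]), residual = sqrt(best$rss),
              degenerate = FALSE, param = NULL)
  class(out) <- "gaussian_response"
  out
}

#' Construct a Gaussian elimination-rate response directly
#'
#' Handy for using a previously calibrated response, e.g. the line-tension
#' response \code{gaussian_response(245, 0.24, 0)} and the contractility
#' response \code{gaussian_response(1800, 0.076, 0)}, as the
#' \eqn{\varepsilon(\zeta)} input of the competition model.
#'
#' @param alpha,beta,gamma curve parameters of
#'   \eqn{\exp[-\alpha(\zeta-\beta)^2] + \gamma}.
#' @param param optional parameter name.
#' @return a \code{gaussian_response} object.
#' @export
gaussian_response <- function(alpha, beta, gamma = 0, param = NULL) {
  stopifnot(alpha >= 0)
  out <- list(alpha = alpha, beta = beta, gamma = gamma, residual = NA_real_,
              degenerate = FALSE, param = param)
  class(out) <- "gaussian_response"
  out
}

#' @export
coef.gaussian_response <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta, gamma = object$gamma)
}

#' @export
predict.gaussian_response <- function(object, newdata, ...) {
  z <- if (is.list(newdata)) newdata[[1]] else newdata
  exp(-object$alpha * (z - object$beta)^2) + object$gamma
}

#' @export
print.gaussian_response <- function(x, ...) {
  cat(sprintf("eps(z) = exp[-%.4g (z - %.4g)^2] + %.4g%s\n",
              x$alpha, x$beta, x$gamma,
              if (isTRUE(x$degenerate)) "  [degenerate: flat data]" else ""))
  if (is.finite(x$residual))
    cat(sprintf("  residual norm %.4g\n", x$residual))
  invisible(x)
}
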
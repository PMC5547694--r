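#' Simulation configuration
#'
#' Builds the full parameter set of the vertex dynamics model in its
#' dimensionless form (lengths in units of the square root of the natural
#' cell area, energies in units of the area elastic modulus). The defaults
#' are the reference parameter set used throughout:
#' \eqn{\Lambda = 0.14}, \eqn{\Gamma = 0.04}, \eqn{\theta_{T1} = 0.1},
#' \eqn{\theta_{T2} = 0.2}, \eqn{\kappa = 0} and growth rate
#' \eqn{\mu = 3.47\times 10^{-3}} (cycle time \eqn{T = \log 2 / \mu}).
#'
#' @param lam0 reference line-tension coefficient \eqn{\Lambda} (dimensionless,
#'   >= 0). Larger values mean stronger edge tension / weaker adhesion and a
#'   less fluid tissue.
#' @param gam0 reference perimeter-contractility coefficient \eqn{\Gamma}
#'   (dimensionless, >= 0).
#' @param theta_T1 edge-length threshold below which a T1 rearrangement fires.
#' @param theta_T2 cell-area threshold below which a cell is extruded
#'   (T2 process).
#' @param kappa concentration of the von Mises distribution of the division
#'   axis around the cell's shortest axis; 0 is isotropic, large values align
#'   division with the shortest axis.
#' @param mu target proliferation rate; the mean cell-cycle length is
#'   \code{log(2) / mu}.
#' @param cycle_jitter fractional uniform randomness of the cycle length
#'   (0.2 means T is drawn uniformly in [0.8, 1.2] times the mean).
#' @param dt explicit-Euler integrator step (dimensionless time).
#' @param eta viscous drag coefficient (1 after nondimensionalisation).
#' @param boundary_tension_mult multiplier of \eqn{\Lambda} on tissue-boundary
#'   edges (3 keeps the tissue outline circular).
#' @param lam_combination rule combining the line tensions of two adjacent
#'   cells with different traits: \code{"max"} or \code{"mean"}.
#' @param mitosis_mode \code{"ramp"}: the natural area grows linearly until the
#'   actual area doubles, then the cell divides; \code{"instant"}: the cell
#'   divides the moment its clock reaches T.
#' @param mitosis_ramp_frac duration of the natural-area ramp (from 1 to 2) as
#'   a fraction of the mean cycle length.
#' @param mitosis_cap_mult force division if the mitotic phase lasts longer
#'   than this multiple of the nominal ramp duration (crowded cells may never
#'   double their area).
#' @param t1_expansion length of the edge created by a T1, as a multiple of
#'   \code{theta_T1}; slightly above 1 so the new edge does not immediately
#'   re-trigger.
#' @param batch_dt time advanced per event batch (clock update, divisions,
#'   relaxation, T1/T2 sweeps).
#' @param relax_force_tol maximum vertex-force norm accepted as mechanical
#'   equilibrium during the per-batch relaxation.
#' @param relax_max_steps cap on Euler steps per relaxation call.
#' @param dilate treat the slow uniform-dilation mode quasi-statically during
#'   relaxation (an exact global-scale line search). Under pure per-vertex
#'   drag the dilation mode slows with tissue area, so a growing tissue
#'   accumulates global compression and the elimination rate rises with size;
#'   with the mode equilibrated the elimination rate stays roughly constant
#'   across growth while the local (neighbourhood-scale) viscous lag — which
#'   carries the growth-rate dependence — is preserved by the finite
#'   \code{relax_max_steps} budget.
#' @param max_disp clamp on the per-step vertex displacement during
#'   relaxation; prevents vertices of a collapsing edge from overshooting past
#'   each other before a T1 sweep resolves the edge.
#' @param init_n number of cells of the initial tissue.
#' @param snapshot_every store a tissue snapshot whenever the cell count has
#'   grown by this many cells.
#' @param track_stress compute the per-cell stress magnitude every batch (needed
#'   for stress feedback and for local stress-change statistics).
#' @param stress_method which discrete stress tensor drives feedback and
#'   per-batch tracking: \code{"B"} (edge-wise, cheap) or \code{"A"}
#'   (boundary-integral).
#' @param feedback list describing stress-dependent regulation; see
#'   \code{\link{feedback_config}}.
#' @param heredity list describing heritable traits; see
#'   \code{\link{heredity_config}}.
#' @param seed integer RNG seed; a run is fully determined by seed + config.
#'
#' @return an object of class \code{sim_config} (a named list).
#' @seealso \code{\link{run_growth}}, \code{\link{generate_initial_tissue}}
#' @export
sim_config <- function(lam0 = 0.14,
                       gam0 = 0.04,
                       theta_T1 = 0.1,
                       theta_T2 = 0.2,
                       kappa = 0,
                       mu = 3.47e-3,
                       cycle_jitter = 0.2,
                       dt = 0.05,
                       eta = 1,
                       boundary_tension_mult = 3,
                       lam_combination = c("max", "mean"),
                       mitosis_mode = c("ramp", "instant"),
                       mitosis_ramp_frac = 0.25,
                       mitosis_cap_mult = 3,
                       t1_expansion = 1.05,
                       batch_dt = 1,
                       relax_force_tol = 2e-3,
                       relax_max_steps = 40,
                       max_disp = 0.1,
                       dilate = TRUE,
                       init_n = 250,
                       snapshot_every = 250,
                       track_stress = TRUE,
                       stress_method = c("B", "A"),
                       feedback = feedback_config(),
                       heredity = heredity_config(),
                       seed = 1L) {
  lam_combination <- match.arg(lam_combination)
  mitosis_mode <- match.arg(mitosis_mode)
  stress_method <- match.arg(stress_method)
  stopifnot(dt > 0, theta_T2 > 0, theta_T2 < 1, kappa >= 0,
            cycle_jitter >= 0, cycle_jitter < 1,
            lam0 >= 0, gam0 >= 0, mu >= 0, eta > 0)
  cfg <- list(
    lam0 = lam0, gam0 = gam0,
    theta_T1 = theta_T1, theta_T2 = theta_T2,
    kappa = kappa, mu = mu,
    cycle_len_mean = if (mu > 0) log(2) / mu else Inf,
    cycle_jitter = cycle_jitter,
    dt = dt, eta = eta,
    boundary_tension_mult = boundary_tension_mult,
    lam_combination = lam_combination,
    mitosis_mode = mitosis_mode,
    mitosis_ramp_frac = mitosis_ramp_frac,
    mitosis_cap_mult = mitosis_cap_mult,
    t1_expansion = t1_expansion,
    batch_dt = batch_dt,
    relax_force_tol = relax_force_tol,
    relax_max_steps = relax_max_steps,
    max_disp = max_disp,
    dilate = dilate,
    init_n = init_n,
    snapshot_every = snapshot_every,
    track_stress = track_stress,
    stress_method = stress_method,
    feedback = feedback,
    heredity = heredity,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Stress-feedback settings
#'
#' @param mode one of \code{"none"}, \code{"growth_gate"} (the cell-cycle clock
#'   runs only while the cell's stress magnitude is at least the pre-growth
#'   tissue mean), \code{"fluidity_self"} / \code{"fluidity_neighbor"}
#'   (contractility or line tension relaxes toward a basal value while being
#'   pushed by the deviation of the cell's stress from a reference, either a
#'   fixed set point or the mean over adjacent cells), or
#'   \code{"division_align"} (the cleavage plane lies along the minimum
#'   principal stress direction).
#' @param c signed feedback strength of the fluidity modes; positive values
#'   suppress cell-size heterogeneity, negative values suppress stress
#'   heterogeneity.
#' @param d restoration rate toward the basal parameter value.
#' @param chi0 basal value of the regulated parameter; defaults to the tissue
#'   reference (\code{gam0} or \code{lam0}) when \code{NULL}.
#' @param target which parameter is regulated, \code{"gam"} or \code{"lam"}.
#' @param S0 reference stress magnitude of \code{"fluidity_self"}; defaults to
#'   the mean interior stress magnitude of the initial relaxed tissue.
#' @param clock_const clock speed of un-gated cells in \code{"growth_gate"}
#'   mode.
#' @return a named list of class \code{feedback_config}.
#' @export
feedback_config <- function(mode = c("none", "growth_gate", "fluidity_self",
                                     "fluidity_neighbor", "division_align"),
                            c = 0.002, d = 0.1, chi0 = NULL,
                            target = c("gam", "lam"),
                            S0 = NULL, clock_const = 1) {
  mode <- match.arg(mode)
  target <- match.arg(target)
  stopifnot(d >= 0, is.null(chi0) || chi0 >= 0)
  structure(list(mode = mode, c = c, d = d, chi0 = chi0, target = target,
                 S0 = S0, clock_const = clock_const),
            class = "feedback_config")
}

#' Heritable-trait settings
#'
#' Cells carry a discrete mechanical trait (a value of the regulated
#' parameter, by default the line tension). At division each daughter copies
#' its parent's trait with probability \code{q} and otherwise draws uniformly
#' from the grid.
#'
#' @param enabled logical; \code{FALSE} gives a pure population.
#' @param q inheritance probability in [0, 1].
#' @param grid ascending trait values; the default spans fluid to marginally
#'   viable line tensions — under the max rule a well-mixed population feels
#'   effective tensions well above its own values, so the grid top stays below
#'   the elimination-dominated regime.
#' @param param which per-cell parameter the trait sets (\code{"lam"} or
#'   \code{"gam"}).
#' @return a named list of class \code{heredity_config}.
#' @export
heredity_config <- function(enabled = FALSE, q = 1,
                            grid = seq(0.02, 0.16, length.out = 10),
                            param = c("lam", "gam")) {
  param <- match.arg(param)
  stopifnot(q >= 0, q <= 1, !is.unsorted(grid))
  structure(list(enabled = enabled, q = q, grid = grid, param = param),
            class = "heredity_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Vertex-model simulation configuration\n")
  cat(sprintf("  Lambda = %g, Gamma = %g, theta_T1 = %g, theta_T2 = %g\n",
              x$lam0, x$gam0, x$theta_T1, x$theta_T2))
  cat(sprintf("  kappa = %g, mu = %g (mean cycle length %.4g)\n",
              x$kappa, x$mu, x$cycle_len_mean))
  cat(sprintf("  dt = %g, batch_dt = %g, mitosis: %s, tension rule: %s\n",
              x$dt, x$batch_dt, x$mitosis_mode, x$lam_combination))
  cat(sprintf("  feedback: %s; heredity: %s; seed: %d\n",
              x$feedback$mode,
              if (isTRUE(x$heredity$enabled))
                sprintf("q = %g, N = %d", x$heredity$q, length(x$heredity$grid))
              else "off",
              x$seed))
  invisible(x)
}
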
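## Stress-dependent regulation laws.

#' Stress-gated cell-cycle rate
#'
#' The cell-cycle clock pauses while the cell's stress magnitude is below the
#' pre-growth tissue mean (compressed cells wait) and otherwise runs at a
#' constant rate.
#'
#' @param S stress magnitude(s) \eqn{\sigma_1 + \sigma_2}.
#' @param Sbar_init mean interior stress magnitude of the tissue before growth
#'   starts.
#' @param clock_const clock rate of un-gated cells.
#' @return clock rate(s), 0 or \code{clock_const}.
#' @export
stress_gated_rate <- function(S, Sbar_init, clock_const = 1) {
  ifelse(S < Sbar_init, 0, clock_const)
}

#' One Euler step of the fluidity feedback
#'
#' The regulated mechanical parameter \eqn{\chi} (contractility or line
#' tension) is pushed by the deviation of the cell's stress magnitude from a
#' reference, and restored toward its basal value:
#' \deqn{d\chi/dt = c\,(S - S_{ref}) - d\,(\chi - \chi^0).}
#' In self mode the reference is a fixed set point; in neighbour mode it is
#' the mean stress magnitude of the adjacent cells. \eqn{\chi} is clipped at 0
#' from below.
#'
#' @param chi current parameter value(s).
#' @param S stress magnitude(s).
#' @param S_ref reference stress (scalar or per cell).
#' @param c feedback strength (signed).
#' @param d restoration rate.
#' @param chi0 basal parameter value.
#' @param dt time step.
#' @return updated \eqn{\chi}, non-negative.
#' @export
fluidity_feedback_step <- function(chi, S, S_ref, c, d, chi0, dt) {
  pmax(chi + dt * (c * (S - S_ref) - d * (chi - chi0)), 0)
}

#' Stress-aligned division axis
#'
#' Returns the cleavage axis lying along the minimum-principal-stress
#' direction of the given stress tensor. For a (near-)isotropic tensor the
#' geometric shortest axis of the cell is used instead.
#'
#' @param tensor symmetric 2 x 2 stress tensor of the cell.
#' @param xy the cell's polygon vertices (fallback geometry).
#' @param tol anisotropy below which the tensor counts as isotropic.
#' @return axis angle in [0, pi).
#' @export
stress_aligned_axis <- function(tensor, xy, tol = 1e-9) {
  pd <- principal_decomposition(tensor)
  if (pd$degenerate || pd$anisotropy < tol) return(shortest_axis(xy)$angle)
  (pd$orientation + pi / 2) %% pi
}
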
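#' Mechanistic osmotic cell-volume model
#'
#' Integrates a two-flux (Kedem--Katchalsky-style) model of cell volume under
#' an osmotic shock: water flux driven by the total osmotic gradient and a
#' permeant-solute (glycerol) flux driven by its concentration gradient,
#'
#' \deqn{dV/dt = P_f A V_w ((N_i + N_g)/V - osm_{out,tot})}
#' \deqn{dN_g/dt = P_{gly} A (c_{out} - N_g/V)}
#'
#' with the impermeant internal content \eqn{N_i = osm_{in,0} V_o} constant,
#' \eqn{V_w = 18} cm^3/mol and constant area. Osmolarities given in osM are
#' converted to mol cm^-3 internally.
#'
#' @param P_f Osmotic water permeability, cm/s (> 0).
#' @param P_gly Permeant (glycerol) permeability, cm/s (>= 0).
#' @param geometry A [cellGeometry()].
#' @param conditions A [shockConditions()].
#' @param t_grid Strictly increasing time grid starting at 0, s.
#' @param rtol,atol Integrator tolerances (lsoda).
#' @return A \code{volumeSeries} data.frame with columns \code{time},
#'   \code{v} (relative volume, \code{v[1] == 1}) and \code{n_g} (internal
#'   permeant per unit initial volume, mol cm^-3).
#' @examples
#' g <- cellGeometry(6.67e-5)
#' sc <- shockConditions(1.4, 1.75)
#' out <- simulateVolumeODE(3.002e-3, 0, g, sc, seq(0, 5, by = 0.01))
#' tail(out$v, 1)   # -> 0.8 (= 1.4/1.75)
#' @export
simulateVolumeODE <- function(P_f, P_gly, geometry, conditions, t_grid,
                              rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(geometry, "cellGeometry"),
            inherits(conditions, "shockConditions"))
  if (!is.numeric(P_f) || P_f <= 0) stop("P_f must be > 0")
  if (!is.numeric(P_gly) || P_gly < 0) stop("P_gly must be >= 0")
  if (length(t_grid) < 2 || t_grid[1] != 0 || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing and start at 0")

  a_over_v0 <- 1 / geometry$V_o_over_A
  osm_in0 <- .osm_to_molcm3(conditions$osm_in_0)
  c_out <- .osm_to_molcm3(conditions$c_out_permeant)
  osm_out_tot <- .osm_to_molcm3(osmOutTotal(conditions))

  deriv <- function(t, y, parms) {
    v <- y[1]; ng <- y[2]
    dv <- P_f * a_over_v0 * .VW * ((osm_in0 + ng) / v - osm_out_tot)
    dng <- P_gly * a_over_v0 * (c_out - ng / v)
    list(c(dv, dng))
  }
  sol <- deSolve::lsoda(c(v = 1, ng = 0), t_grid, deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integrator failed before t = ", max(sol[, "time"]))
  v <- sol[, "v"]
  if (any(v <= 0)) {
    bad <- sol[which(v <= 0)[1], "time"]
    stop("non-positive relative volume at t = ", bad, " s")
  }
  structure(data.frame(time = sol[, "time"], v = v, n_g = sol[, "ng"]),
            class = c("volumeSeries", "data.frame"))
}

#' Closed-form equilibrium relative volume
#'
#' The analytic end point of an osmotic shock. If the permeant does not
#' equilibrate (or there is none), the cell equilibrates against the total
#' external osmolarity: \eqn{v_\infty = osm_{in,0}/osm_{out,tot}}. If the
#' permeant fully equilibrates, only the impermeant fraction matters:
#' \eqn{v_\infty = osm_{in,0}/osm_{out,imp}}.
#'
#' @param conditions A [shockConditions()].
#' @param permeant_equilibrates Logical; does the permeant reach its external
#'   concentration at equilibrium?
#' @return Relative equilibrium volume (dimensionless).
#' @export
equilibriumVolume <- function(conditions, permeant_equilibrates = FALSE) {
  stopifnot(inherits(conditions, "shockConditions"))
  if (permeant_equilibrates) {
    if (conditions$osm_out_impermeant <= 0)
      stop("no finite equilibrium: permeant equilibrates but impermeant external osmolarity is 0")
    conditions$osm_in_0 / conditions$osm_out_impermeant
  } else {
    tot <- osmOutTotal(conditions)
    if (tot <= 0) stop("osm_out_total must be > 0")
    conditions$osm_in_0 / tot
  }
}

#' Linearized single-exponential rate constant
#'
#' The algebraic inverse of the permeability formulas: the rate constant a
#' single-exponential fit would recover from a small shock.
#' Water: \eqn{k = P_f (A/V_o) V_w osm_{out,tot}} (osM converted to
#' mol cm^-3); glycerol: \eqn{k = P_{gly} (A/V_o)}.
#'
#' @param P Permeability, cm/s (> 0).
#' @param geometry A [cellGeometry()].
#' @param conditions A [shockConditions()] (used for water only).
#' @param kind \code{"water"} or \code{"glycerol"}.
#' @return Rate constant, s^-1.
#' @examples
#' g <- cellGeometry(6.67e-5)
#' linearizedRate(3.002e-3, g, shockConditions(1.4, 1.75), "water")  # 1.418
#' linearizedRate(4.54e-6, g, kind = "glycerol")                     # 0.0681
#' @export
linearizedRate <- function(P, geometry, conditions = NULL,
                           kind = c("water", "glycerol")) {
  kind <- match.arg(kind)
  stopifnot(inherits(geometry, "cellGeometry"))
  if (!is.numeric(P) || P <= 0) stop("P must be > 0")
  if (kind == "water") {
    stopifnot(inherits(conditions, "shockConditions"))
    P / geometry$V_o_over_A * .VW * .osm_to_molcm3(osmOutTotal(conditions))
  } else {
    P / geometry$V_o_over_A
  }
}
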
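#' Cell geometry for permeability calculations
#'
#' The only geometric quantity the permeability formulas need is the initial
#' volume-to-area ratio \eqn{V_o/A} (cm). \code{V_o} and \code{A} may be given
#' individually, in which case they must be consistent with \code{V_o_over_A}
#' to within 1e-9 relative.
#'
#' @param V_o_over_A Initial cell volume to area ratio, cm.
#' @param V_o Optional initial cell volume, cm^3.
#' @param A Optional initial cell surface area, cm^2.
#' @return An object of class \code{cellGeometry}.
#' @examples
#' cellGeometry(6.67e-5)
#' @export
cellGeometry <- function(V_o_over_A = NULL, V_o = NULL, A = NULL) {
  if (is.null(V_o_over_A)) {
    if (is.null(V_o) || is.null(A))
      stop("supply V_o_over_A, or both V_o and A")
    V_o_over_A <- V_o / A
  }
  if (!is.numeric(V_o_over_A) || length(V_o_over_A) != 1L || V_o_over_A <= 0)
    stop("V_o_over_A must be a single positive number (cm)")
  if (!is.null(V_o) && !is.null(A)) {
    if (abs(V_o / A - V_o_over_A) > 1e-9 * V_o_over_A)
      stop("V_o/A inconsistent with V_o_over_A (tolerance 1e-9 relative)")
  }
  structure(list(V_o_over_A = V_o_over_A, V_o = V_o, A = A),
            class = "cellGeometry")
}

#' @export
print.cellGeometry <- function(x, ...) {
  cat(sprintf("cellGeometry: V_o/A = %g cm\n", x$V_o_over_A))
  invisible(x)
}

#' Osmotic shock boundary conditions
#'
#' Describes one stopped-flow mixing experiment: the initial internal
#' osmolarity and the external osmolarities *after* the 1:1 mix with the shock
#' solution. The total external osmolarity
#' \code{osm_out_impermeant + c_out_permeant} is the \eqn{(osm_{out})_\infty}
#' entering the water-permeability formula.
#'
#' @param osm_in_0 Initial internal osmolarity, osM.
#' @param osm_out_impermeant External impermeant osmolarity after mixing, osM.
#' @param c_out_permeant External permeant (glycerol) concentration after
#'   mixing, osM. Default 0 (impermeant-only shock).
#' @param temperature Temperature, K.
#' @return An object of class \code{shockConditions}.
#' @examples
#' shockConditions(1.4, 1.75)              # yeast sorbitol shock
#' shockConditions(0.3, 0.3, 0.1)          # RBC glycerol shock
#' @export
shockConditions <- function(osm_in_0, osm_out_impermeant,
                            c_out_permeant = 0, temperature = 296.15) {
  vals <- c(osm_in_0 = osm_in_0, osm_out_impermeant = osm_out_impermeant,
            c_out_permeant = c_out_permeant)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("osmolarities/concentrations must be finite and >= 0")
  if (osm_in_0 <= 0)
    stop("osm_in_0 must be > 0")
  structure(list(osm_in_0 = osm_in_0,
                 osm_out_impermeant = osm_out_impermeant,
                 c_out_permeant = c_out_permeant,
                 temperature = temperature),
            class = "shockConditions")
}

#' Total external osmolarity of a shock
#'
#' @param conditions A [shockConditions()] object.
#' @return \code{osm_out_impermeant + c_out_permeant}, osM.
#' @export
osmOutTotal <- function(conditions) {
  stopifnot(inherits(conditions, "shockConditions"))
  conditions$osm_out_impermeant + conditions$c_out_permeant
}

#' @export
print.shockConditions <- function(x, ...) {
  cat(sprintf(
    "shockConditions: osm_in,0 = %g osM; out = %g osM impermeant + %g osM permeant (total %g); T = %g K\n",
    x$osm_in_0, x$osm_out_impermeant, x$c_out_permeant, osmOutTotal(x),
    x$temperature))
  invisible(x)
}
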
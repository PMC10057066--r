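# Rate constant -> permeability conversion and comparative statistics.

.newPermeabilityResult <- function(kind, P, P_stderr, k, geometry,
                                   conditions = NULL) {
  structure(list(kind = kind, P = P, P_stderr = P_stderr, k = k,
                 geometry = geometry, conditions = conditions),
            class = "permeabilityResult")
}

#' @export
print.permeabilityResult <- function(x, ...) {
  cat(sprintf("permeabilityResult (%s): P = %.4g +/- %.2g cm/s (k = %.4g s^-1)\n",
              x$kind, x$P, x$P_stderr, x$k))
  invisible(x)
}

#' Osmotic water permeability from a shrinkage rate constant
#'
#' \deqn{P_f = k (V_o/A) / (V_w (osm_{out})_\infty)}
#' with \eqn{V_w = 18} cm^3/mol and the final external osmolarity converted
#' from osM to mol cm^-3. The standard error is scaled by the same factor,
#' so \code{P_stderr/P == k_stderr/k} exactly.
#'
#' @param k Shrinkage rate constant, s^-1 (>= 0), or an `exponentialFit`.
#' @param geometry A [cellGeometry()].
#' @param conditions A [shockConditions()]; its total external osmolarity is
#'   \eqn{(osm_{out})_\infty}.
#' @param k_stderr Standard error of `k` (ignored when `k` is a fit).
#' @return A `permeabilityResult`.
#' @examples
#' g <- cellGeometry(6.67e-5)
#' waterPermeability(1.418, g, shockConditions(1.4, 1.75))$P  # ~3.0e-3
#' @export
waterPermeability <- function(k, geometry, conditions, k_stderr = 0) {
  if (inherits(k, "exponentialFit")) { k_stderr <- k$k_stderr; k <- k$k }
  stopifnot(inherits(geometry, "cellGeometry"),
            inherits(conditions, "shockConditions"))
  if (k < 0) stop("k must be >= 0")
  tot <- .osm_to_molcm3(osmOutTotal(conditions))
  if (tot <= 0) stop("osm_out_total must be > 0")
  fac <- geometry$V_o_over_A / (.VW * tot)
  .newPermeabilityResult("water", k * fac, k_stderr * fac, k, geometry,
                         conditions)
}

#' Glycerol permeability from a reswelling rate constant
#'
#' \deqn{P_{gly} = k (V_o/A)}
#'
#' @inheritParams waterPermeability
#' @param k Reswelling rate constant, s^-1 (>= 0), or an `exponentialFit`.
#' @return A `permeabilityResult`.
#' @examples
#' glycerolPermeability(0.0681, cellGeometry(6.67e-5))$P  # ~4.54e-6
#' @export
glycerolPermeability <- function(k, geometry, k_stderr = 0) {
  if (inherits(k, "exponentialFit")) { k_stderr <- k$k_stderr; k <- k$k }
  stopifnot(inherits(geometry, "cellGeometry"))
  if (k < 0) stop("k must be >= 0")
  fac <- geometry$V_o_over_A
  .newPermeabilityResult("glycerol", k * fac, k_stderr * fac, k, geometry)
}

.asP <- function(x) if (inherits(x, "permeabilityResult")) x$P else x

#' Percent inhibition between control and treated permeabilities
#'
#' `100 * (1 - P_treated / P_control)`. Negative values (activation) are
#' returned, not clipped.
#'
#' @param P_control,P_treated `permeabilityResult`s of the same kind, or
#'   bare numbers.
#' @return Percent inhibition.
#' @export
percentInhibition <- function(P_control, P_treated) {
  if (inherits(P_control, "permeabilityResult") &&
      inherits(P_treated, "permeabilityResult") &&
      P_control$kind != P_treated$kind)
    stop("kind mismatch: ", P_control$kind, " vs ", P_treated$kind)
  pc <- .asP(P_control); pt <- .asP(P_treated)
  if (pc <= 0) stop("control permeability must be > 0")
  100 * (1 - pt / pc)
}

#' Fold change between two permeabilities
#'
#' @param P_a,P_b `permeabilityResult`s of the same kind, or bare numbers;
#'   returns `P_a / P_b`.
#' @return The ratio.
#' @export
foldChange <- function(P_a, P_b) {
  if (inherits(P_a, "permeabilityResult") &&
      inherits(P_b, "permeabilityResult") && P_a$kind != P_b$kind)
    stop("kind mismatch: ", P_a$kind, " vs ", P_b$kind)
  pa <- .asP(P_a); pb <- .asP(P_b)
  if (pb <= 0) stop("denominator permeability must be > 0")
  pa / pb
}
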
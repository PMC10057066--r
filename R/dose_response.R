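# Hill dose-response model and IC50 estimation.

#' Hill inhibition model
#'
#' \deqn{y = 100 / (1 + 10^{(LogIC50 - X) \cdot HillSlope})}
#' with \eqn{X = \log_{10}(concentration)}. `y` is percent inhibition,
#' strictly increasing in concentration for positive slopes, with
#' `y(IC50) = 50` exactly.
#'
#' @param concentration Inhibitor concentration(s), uM (> 0).
#' @param LogIC50 log10 of the IC50 (same concentration units).
#' @param HillSlope Steepness parameter.
#' @return Percent inhibition in (0, 100).
#' @examples
#' hillInhibition(25, log10(6.7), 3.5)    # ~99.0
#' hillInhibition(25, log10(22.8), 1.0)   # ~52.3
#' @export
hillInhibition <- function(concentration, LogIC50, HillSlope) {
  if (any(concentration <= 0)) stop("concentration must be > 0")
  100 / (1 + 10^((LogIC50 - log10(concentration)) * HillSlope))
}

#' Fit the Hill inhibition model to dose--response data
#'
#' Unweighted nonlinear least squares of `(LogIC50, HillSlope)` in the
#' fixed-asymptote (0--100) Hill model. Initialization is deterministic:
#' `LogIC50` starts at the X of the point with inhibition closest to 50,
#' `HillSlope` at 1; bounds are `HillSlope` in [0.1, 10] and `LogIC50`
#' within the data range +/- 1 decade. The 95% CI on IC50 is computed by
#' profile likelihood (see [ic50ConfidenceInterval()] for the bootstrap
#' alternative).
#'
#' @param points Data frame with columns `concentration` (uM, > 0) and
#'   `inhibition` (percent); an optional `replicate` column is carried
#'   along for bootstrap resampling.
#' @return A `doseResponseFit`: `list(IC50, LogIC50, HillSlope, cov,
#'   ci (uM), residual_rms, points, fit)`.
#' @export
fitIC50 <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("concentration", "inhibition") %in% names(points)))
  if (any(points$concentration <= 0)) stop("concentrations must be > 0")
  x <- log10(points$concentration)
  y <- points$inhibition
  if (length(unique(points$concentration)) < 3)
    stop("need at least 3 distinct concentrations")
  if (diff(range(y)) < 20)
    stop("unidentifiable: inhibition values span less than 20 percentage points")

  l0 <- x[which.min(abs(y - 50))]
  lower <- c(LogIC50 = min(x) - 1, HillSlope = 0.1)
  upper <- c(LogIC50 = max(x) + 1, HillSlope = 10)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ 100 / (1 + 10^((LogIC50 - x) * HillSlope)),
      start = list(LogIC50 = l0, HillSlope = 1),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("Hill fit did not converge: ",
                             conditionMessage(e)))
  est <- stats::coef(fit)
  res <- stats::residuals(fit)
  out <- structure(
    list(IC50 = 10^unname(est["LogIC50"]),
         LogIC50 = unname(est["LogIC50"]),
         HillSlope = unname(est["HillSlope"]),
         cov = stats::vcov(fit),
         ci = c(NA_real_, NA_real_),
         residual_rms = sqrt(mean(res^2)),
         points = points, fit = fit),
    class = "doseResponseFit")
  out$ci <- tryCatch(.profileCI(out), error = function(e) c(NA, NA))
  out
}

#' @export
print.doseResponseFit <- function(x, ...) {
  cat(sprintf("doseResponseFit: IC50 = %.4g uM (95%% CI %.4g-%.4g), HillSlope = %.3g\n",
              x$IC50, x$ci[1], x$ci[2], x$HillSlope))
  invisible(x)
}

# Profile-likelihood 95% CI on LogIC50: refit HillSlope on a marching grid
# of fixed LogIC50, find where RSS crosses RSS0 * (1 + qF/(n-2)).
.profileCI <- function(fit, level = 0.95) {
  pts <- fit$points
  x <- log10(pts$concentration)
  y <- pts$inhibition
  n <- length(y)
  df <- n - 2
  rss0 <- sum(stats::residuals(fit$fit)^2)
  thr <- rss0 * (1 + stats::qf(level, 1, df) / df)
  rss_at <- function(L) {
    f <- tryCatch(minpack.lm::nlsLM(
      y ~ 100 / (1 + 10^((L - x) * HillSlope)),
      start = list(HillSlope = max(min(fit$HillSlope, 10), 0.1)),
      lower = c(HillSlope = 0.1), upper = c(HillSlope = 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(f)) Inf else sum(stats::residuals(f)^2)
  }
  march <- function(dir) {
    step <- max(0.02, sqrt(fit$cov["LogIC50", "LogIC50"]) / 2)
    L <- fit$LogIC50
    for (i in 1:200) {
      Lnew <- L + dir * step
      if (rss_at(Lnew) > thr) {
        root <- stats::uniroot(function(z) rss_at(z) - thr, c(min(L, Lnew),
                                                              max(L, Lnew)),
                               tol = 1e-6)$root
        return(root)
      }
      L <- Lnew
      if (abs(L - fit$LogIC50) > 6) return(dir * Inf)  # unbounded side
    }
    dir * Inf
  }
  lims <- sort(c(march(-1), march(1)))
  10^lims
}

#' Confidence interval for a fitted IC50
#'
#' `method = "profile"` recomputes the profile-likelihood interval;
#' `method = "bootstrap"` performs seeded case resampling -- whole
#' replicates when a `replicate` column is present, otherwise individual
#' points -- and returns the percentile interval of the refitted IC50s.
#'
#' @param fit A [fitIC50()] result.
#' @param points Data used for the fit (defaults to `fit$points`).
#' @param method `"profile"` or `"bootstrap"`.
#' @param n_boot Bootstrap resamples (>= 100).
#' @param seed Integer seed for the bootstrap.
#' @param level Confidence level.
#' @return Length-2 numeric interval on the IC50 (uM) scale.
#' @export
ic50ConfidenceInterval <- function(fit, points = fit$points,
                                   method = c("profile", "bootstrap"),
                                   n_boot = 1000, seed = 1, level = 0.95) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "doseResponseFit"))
  if (method == "profile") return(.profileCI(fit, level))
  if (n_boot < 100) stop("n_boot must be >= 100")
  groups <- if ("replicate" %in% names(points))
    split(seq_len(nrow(points)), points$replicate)
  else as.list(seq_len(nrow(points)))
  ics <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      take <- unlist(groups[sample.int(length(groups), replace = TRUE)])
      f <- tryCatch(fitIC50(points[take, , drop = FALSE]),
                    error = function(e) NULL)
      if (is.null(f)) NA_real_ else f$IC50
    }, numeric(1))
  })
  ics <- ics[is.finite(ics)]
  if (length(ics) < n_boot / 2)
    stop("bootstrap failed: too many non-convergent resamples")
  unname(stats::quantile(ics, c((1 - level) / 2, 1 - (1 - level) / 2)))
}
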
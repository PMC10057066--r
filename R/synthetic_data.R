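# Synthetic stopped-flow traces and MD-style fixtures. All randomness is
# routed through withr::with_seed so the global RNG is never touched and
# identical (arguments, seed) give identical output.

# signal-mapping constants: scatter S = s0 + s1 (1 - v); fluorescence
# F = f0 v (1 - bleach_rate t). Monotone affine maps of v preserve fitted
# rate constants.
.SCATTER_S0 <- 0.2
.SCATTER_S1 <- 1.0
.FLUOR_F0 <- 1.0

.newVolumeTrace <- function(time, signal, modality, conditions, geometry,
                            meta = list()) {
  if (length(time) < 10) stop("a trace needs at least 10 points")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (any(!is.finite(signal))) stop("signal contains NaN/Inf")
  structure(list(time = time, signal = signal, modality = modality,
                 conditions = conditions, geometry = geometry, meta = meta),
            class = "volumeTrace")
}

#' @export
print.volumeTrace <- function(x, ...) {
  cat(sprintf("volumeTrace (%s): %d points over %g s\n",
              x$modality, length(x$time), max(x$time)))
  invisible(x)
}

.mapSignal <- function(v, t, modality, bleach_rate) {
  if (modality == "scatter") {
    .SCATTER_S0 + .SCATTER_S1 * (1 - v)
  } else {
    .FLUOR_F0 * v * (1 - bleach_rate * t)
  }
}

#' Generate a synthetic water-shock (shrinkage) trace
#'
#' In the default formula-consistent mode the underlying relative volume is
#' the exact single exponential \eqn{v(t) = v_\infty + (1 - v_\infty)
#' e^{-k_w t}} with \eqn{k_w} the linearized water rate and
#' \eqn{v_\infty = osm_{in,0}/osm_{out,\infty}}, so the inverse formulas are
#' exact on noiseless data. `mode = "ode"` integrates the mechanistic model
#' instead. The signal is the modality mapping of `v(t)` plus Gaussian noise
#' (SD = `noise_sd` x shock amplitude) and, for fluorescence, linear bleach
#' drift. Ground truth (`P_f`, `k_w`, `v_inf`, ...) is stored in `$meta` for
#' closed-loop recovery tests.
#'
#' @param preset A [generatorPreset()].
#' @param duration Trace length, s (> 0).
#' @param n_points Number of samples (>= 10).
#' @param seed Integer seed.
#' @param mode `"formula"` (default) or `"ode"`.
#' @param shock Shock conditions; defaults to `preset$shock_water`.
#' @return A `volumeTrace`.
#' @export
generateWaterTrace <- function(preset, duration, n_points = 500, seed = 1,
                               mode = c("formula", "ode"),
                               shock = preset$shock_water) {
  mode <- match.arg(mode)
  stopifnot(inherits(preset, "generatorPreset"))
  if (duration <= 0) stop("duration must be > 0")
  if (n_points < 10) stop("n_points must be >= 10")
  .checkHyperosmotic(shock)

  t <- seq(0, duration, length.out = n_points)
  k_w <- linearizedRate(preset$P_f, preset$geometry, shock, "water")
  v_inf <- shock$osm_in_0 / osmOutTotal(shock)
  v <- if (mode == "formula") {
    v_inf + (1 - v_inf) * exp(-k_w * t)
  } else {
    simulateVolumeODE(preset$P_f, 0, preset$geometry, shock, t)$v
  }
  .emitTrace(v, t, preset, shock, seed,
             meta = list(kind = "water", P_f = preset$P_f, k_w = k_w,
                         v_inf = v_inf, mode = mode, seed = seed))
}

#' Generate a synthetic glycerol-shock (biphasic) trace
#'
#' Default formula-consistent mode emits the two-rate cascade
#' \deqn{v(t) = 1 - a \frac{k_w}{k_w - k_g}(e^{-k_g t} - e^{-k_w t})}
#' with \eqn{a = 1 - v_\infty}, \eqn{k_g = P_{gly}/(V_o/A)}: fast osmotic
#' shrinkage followed by glycerol-driven reswelling toward the initial
#' volume. Requires \eqn{k_w > k_g} (water equilibrates faster than
#' glycerol); the degenerate \eqn{k_w = k_g} case is rejected explicitly.
#'
#' @inheritParams generateWaterTrace
#' @param shock Shock conditions; defaults to `preset$shock_glycerol`.
#' @return A `volumeTrace` with true `k_g` (and `k_w`) in `$meta`.
#' @export
generateGlycerolTrace <- function(preset, duration, n_points = 500, seed = 1,
                                  mode = c("formula", "ode"),
                                  shock = preset$shock_glycerol) {
  mode <- match.arg(mode)
  stopifnot(inherits(preset, "generatorPreset"))
  if (duration <= 0) stop("duration must be > 0")
  if (n_points < 10) stop("n_points must be >= 10")
  if (preset$P_gly <= 0) stop("preset P_gly must be > 0 for a glycerol trace")
  if (shock$c_out_permeant <= 0)
    stop("glycerol shock needs a permeant concentration > 0")
  .checkHyperosmotic(shock)

  t <- seq(0, duration, length.out = n_points)
  k_w <- linearizedRate(preset$P_f, preset$geometry, shock, "water")
  k_g <- linearizedRate(preset$P_gly, preset$geometry, kind = "glycerol")
  if (k_w == k_g)
    stop("degenerate case k_w == k_g: cascade form undefined")
  if (k_w < k_g)
    stop("k_w <= k_g: water must equilibrate faster than glycerol")
  v_inf <- shock$osm_in_0 / osmOutTotal(shock)
  a <- 1 - v_inf
  v <- if (mode == "formula") {
    1 - a * (k_w / (k_w - k_g)) * (exp(-k_g * t) - exp(-k_w * t))
  } else {
    simulateVolumeODE(preset$P_f, preset$P_gly, preset$geometry, shock, t)$v
  }
  .emitTrace(v, t, preset, shock, seed,
             meta = list(kind = "glycerol", P_f = preset$P_f,
                         P_gly = preset$P_gly, k_w = k_w, k_g = k_g,
                         v_inf = v_inf, mode = mode, seed = seed))
}

.checkHyperosmotic <- function(shock) {
  if (osmOutTotal(shock) <= 0 || shock$osm_in_0 <= 0)
    stop("osmolarities must be positive")
  if (osmOutTotal(shock) <= shock$osm_in_0)
    stop("shock must be hyperosmotic: osm_out_total > osm_in_0")
}

.emitTrace <- function(v, t, preset, shock, seed, meta) {
  amplitude <- abs(1 - meta$v_inf) *
    if (preset$modality == "scatter") .SCATTER_S1 else .FLUOR_F0
  clean <- .mapSignal(v, t, preset$modality, preset$bleach_rate)
  noise <- if (preset$noise_sd > 0) {
    withr::with_seed(seed,
      stats::rnorm(length(t), sd = preset$noise_sd * amplitude))
  } else 0
  meta$noise_sd_abs <- preset$noise_sd * amplitude
  meta$bleach_rate <- preset$bleach_rate
  meta$preset <- preset$name
  .newVolumeTrace(t, clean + noise, preset$modality, shock,
                  preset$geometry, meta)
}

#' Generate an isotonic baseline trace
#'
#' Emulates the baseline acquisition of a stopped-flow experiment: the cell
#' suspension is mixed with its own (isotonic) incubation buffer, so the
#' volume stays at 1 and the recorded signal is flat apart from noise and,
#' for fluorescence, the linear bleach drift. Used by [correctBleaching()].
#'
#' @inheritParams generateWaterTrace
#' @return A `volumeTrace` with constant underlying volume.
#' @export
generateBaselineTrace <- function(preset, duration, n_points = 500,
                                  seed = 1) {
  stopifnot(inherits(preset, "generatorPreset"))
  if (duration <= 0) stop("duration must be > 0")
  if (n_points < 10) stop("n_points must be >= 10")
  t <- seq(0, duration, length.out = n_points)
  v <- rep(1, n_points)
  shock <- shockConditions(preset$shock_water$osm_in_0,
                           preset$shock_water$osm_in_0, 0,
                           preset$shock_water$temperature)
  # noise scaled to the water-shock amplitude so baseline and shock traces
  # share a noise level
  v_inf <- preset$shock_water$osm_in_0 / osmOutTotal(preset$shock_water)
  .emitTrace(v, t, preset, shock, seed,
             meta = list(kind = "baseline", v_inf = v_inf, mode = "formula",
                         seed = seed))
}

#' Generate a full dose--response trace set
#'
#' For each concentration, generates `replicates` control traces and
#' `replicates` treated traces whose permeabilities are reduced by the
#' preset's Hill inhibition model evaluated at that concentration. Per-trace
#' seeds are drawn deterministically from the master seed, so the whole set
#' is reproducible and replicate traces differ only in their noise
#' realization.
#'
#' @param preset A [generatorPreset()] with a Hill-type inhibition entry for
#'   the requested kind.
#' @param concentrations Inhibitor concentrations, uM (all > 0).
#' @param replicates Traces per arm and concentration (>= 1).
#' @param seed Master seed.
#' @param kind `"glycerol"` or `"water"`: which assay to simulate.
#' @param duration,n_points Trace sampling, passed to the generators.
#' @return A `doseResponseSet`: list with one element per concentration,
#'   each `list(concentration, true_inhibition, control, treated)` where the
#'   arms are lists of `volumeTrace`s.
#' @export
generateDoseResponseSet <- function(preset, concentrations, replicates = 5,
                                    seed = 1,
                                    kind = c("glycerol", "water"),
                                    duration = NULL, n_points = 500) {
  kind <- match.arg(kind)
  stopifnot(inherits(preset, "generatorPreset"))
  if (any(concentrations <= 0)) stop("concentrations must all be > 0")
  if (replicates < 1) stop("replicates must be >= 1")
  pkey <- if (kind == "glycerol") "P_gly" else "P_f"
  if (is.null(preset$inhibition) || is.null(preset$inhibition[[pkey]]))
    stop("preset has no inhibition model for ", pkey)

  gen <- if (kind == "glycerol") generateGlycerolTrace else generateWaterTrace
  if (is.null(duration)) {
    k0 <- if (kind == "glycerol")
      linearizedRate(preset$P_gly, preset$geometry, kind = "glycerol")
    else
      linearizedRate(preset$P_f, preset$geometry, preset$shock_water, "water")
    duration <- 6 / k0
  }
  n_seeds <- length(concentrations) * replicates * 2L
  seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 1L, n_seeds))
  si <- 0L
  nxt <- function() { si <<- si + 1L; seeds[si] }

  out <- lapply(seq_along(concentrations), function(i) {
    conc <- concentrations[i]
    trt <- treatedPreset(preset, conc)
    frac <- trt$applied_inhibition[[pkey]]
    control <- lapply(seq_len(replicates), function(r)
      gen(preset, duration, n_points, seed = nxt()))
    treated <- lapply(seq_len(replicates), function(r)
      gen(trt, duration, n_points, seed = nxt()))
    list(concentration = conc, true_inhibition = 100 * frac,
         control = control, treated = treated)
  })
  structure(out, class = "doseResponseSet", kind = kind,
            preset = preset$name, seed = seed)
}

#' Sample (d1, d2) collective-variable pairs from a Gaussian mixture
#'
#' Stands in for MD-sampled inter-loop distances: draws `n` points from a
#' 2D Gaussian mixture and tags them with synthetic frame/monomer/replicate
#' ids. The generating mixture and component assignments are recorded as
#' attributes for recovery tests.
#'
#' @param mixture List of components, each
#'   `list(weight, mean = c(d1, d2), cov = 2x2 matrix)` (a scalar or
#'   length-2 `cov` is taken as a diagonal). Weights must be positive and
#'   sum to 1; covariances positive-definite.
#' @param n Number of samples (>= 1).
#' @param seed Integer seed.
#' @param n_monomers,n_replicates Synthetic id layout (frames cycle through
#'   monomers, then replicates).
#' @return A `cvSamples` data.frame with columns `frame`, `monomer`,
#'   `replicate`, `time_ns`, `d1`, `d2`.
#' @export
generateCVSamples <- function(mixture, n, seed = 1, n_monomers = 4,
                              n_replicates = 5) {
  if (n < 1) stop("n must be >= 1")
  w <- vapply(mixture, `[[`, 0, "weight")
  if (any(w <= 0) || abs(sum(w) - 1) > 1e-8)
    stop("mixture weights must be positive and sum to 1")
  covs <- lapply(mixture, function(m) {
    cv <- m$cov
    if (is.null(dim(cv))) cv <- diag(rep(cv, length.out = 2))
    if (any(eigen(cv, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stop("mixture covariance must be positive-definite")
    cv
  })
  xy <- withr::with_seed(seed, {
    comp <- sample.int(length(mixture), n, replace = TRUE, prob = w)
    pts <- matrix(0, n, 2)
    for (j in seq_along(mixture)) {
      idx <- which(comp == j)
      if (length(idx))
        pts[idx, ] <- MASS::mvrnorm(length(idx), mixture[[j]]$mean, covs[[j]])
    }
    list(pts = pts, comp = comp)
  })
  mono <- ((seq_len(n) - 1L) %% n_monomers) + 1L
  repl <- (((seq_len(n) - 1L) %/% n_monomers) %% n_replicates) + 1L
  out <- data.frame(frame = seq_len(n), monomer = mono, replicate = repl,
                    time_ns = as.numeric(seq_len(n)),
                    d1 = xy$pts[, 1], d2 = xy$pts[, 2])
  structure(out, class = c("cvSamples", "data.frame"),
            mixture = mixture, component = xy$comp, seed = seed)
}

#' Generate a toy multi-frame protein--ligand complex
#'
#' Builds a small synthetic coordinate set for contact-analysis tests: one
#' C-alpha pseudo-atom per listed residue (chain A), jittered independently
#' per frame, plus a single-atom ligand (residue name `LIG`, chain B)
#' following `ligand_path`. Positions are given in nm and stored in
#' Angstrom, as in PDB files.
#'
#' @param n_frames Number of frames (>= 1).
#' @param residue_layout List of `list(resno, pos = c(x, y, z), jitter)`
#'   with `pos` in nm and `jitter` an isotropic Gaussian SD in nm.
#' @param ligand_path Either a single `c(x, y, z)` (nm, held fixed) or an
#'   `n_frames x 3` matrix of per-frame positions.
#' @param seed Integer seed for the jitter.
#' @return An `mdFrames` object: `list(atoms, xyz, times_ns)` with `atoms` a
#'   data.frame (serial, elety, resid, chain, resno) and `xyz` an
#'   `n_frames x 3*n_atoms` matrix in Angstrom.
#' @export
generateToyComplex <- function(n_frames, residue_layout, ligand_path,
                               seed = 1) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  nres <- length(residue_layout)
  if (nres < 1) stop("residue_layout must be non-empty")
  if (is.null(dim(ligand_path)))
    ligand_path <- matrix(ligand_path, n_frames, 3, byrow = TRUE)
  if (nrow(ligand_path) != n_frames)
    stop("ligand_path must have one position per frame")

  n_atoms <- nres + 1L
  serial <- seq_len(n_atoms)
  if (anyDuplicated(serial)) stop("overlapping atom serial numbers")
  atoms <- data.frame(
    serial = serial,
    elety = c(rep("CA", nres), "C1"),
    resid = c(rep("ALA", nres), "LIG"),
    chain = c(rep("A", nres), "B"),
    resno = c(vapply(residue_layout, function(r) as.integer(r$resno), 1L),
              9999L),
    stringsAsFactors = FALSE)
  base <- t(vapply(residue_layout, function(r) as.numeric(r$pos),
                   numeric(3)))
  jit <- vapply(residue_layout, function(r)
    if (is.null(r$jitter)) 0 else r$jitter, 0)

  xyz <- withr::with_seed(seed, {
    m <- matrix(0, n_frames, 3L * n_atoms)
    for (f in seq_len(n_frames)) {
      prot <- base + matrix(stats::rnorm(3 * nres, sd = rep(jit, 3)),
                            nres, 3)
      coords <- rbind(prot, ligand_path[f, , drop = FALSE])
      m[f, ] <- as.numeric(t(coords)) * 10  # nm -> Angstrom
    }
    m
  })
  structure(list(atoms = atoms, xyz = xyz,
                 times_ns = as.numeric(seq_len(n_frames))),
            class = "mdFrames")
}

#' @export
print.mdFrames <- function(x, ...) {
  cat(sprintf("mdFrames: %d frames, %d atoms (%d ligand)\n",
              nrow(x$xyz), nrow(x$atoms), sum(x$atoms$resid == "LIG")))
  invisible(x)
}
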
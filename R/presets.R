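#' Construct a synthetic-trace generator preset
#'
#' A preset bundles everything the trace generator needs for one cell
#' system: true permeabilities, geometry, water- and glycerol-shock
#' conditions, the recorded modality and its noise/bleach model, and
#' optionally an inhibition model used to derive "treated" variants.
#'
#' `inhibition` is a named list with optional entries `P_f` and `P_gly`,
#' each either a single fraction in `[0, 1]` (fixed fractional reduction of
#' that permeability under treatment) or a list `list(IC50 = ..., HillSlope
#' = ...)` (concentration-dependent reduction following the Hill model).
#'
#' @param name Preset identifier.
#' @param P_f True water permeability, cm/s (> 0).
#' @param P_gly True glycerol permeability, cm/s (>= 0; 0 for water-only
#'   channels).
#' @param geometry A [cellGeometry()].
#' @param shock_water,shock_glycerol [shockConditions()] for the two assays.
#' @param modality `"scatter"` or `"fluorescence"`.
#' @param noise_sd Gaussian noise SD as a fraction of the shock signal
#'   amplitude (>= 0).
#' @param bleach_rate Fractional fluorescence loss per second (>= 0;
#'   fluorescence only).
#' @param inhibition Optional inhibition model (see Details).
#' @return An object of class `generatorPreset`.
#' @export
generatorPreset <- function(name, P_f, P_gly, geometry, shock_water,
                            shock_glycerol,
                            modality = c("scatter", "fluorescence"),
                            noise_sd = 0.02, bleach_rate = 0,
                            inhibition = NULL) {
  modality <- match.arg(modality)
  stopifnot(inherits(geometry, "cellGeometry"),
            inherits(shock_water, "shockConditions"),
            inherits(shock_glycerol, "shockConditions"))
  if (!is.numeric(P_f) || P_f <= 0) stop("P_f must be > 0")
  if (!is.numeric(P_gly) || P_gly < 0) stop("P_gly must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (bleach_rate < 0) stop("bleach_rate must be >= 0")
  if (!is.null(inhibition)) {
    if (!is.list(inhibition) ||
        !all(names(inhibition) %in% c("P_f", "P_gly")))
      stop("inhibition must be a named list with entries P_f and/or P_gly")
    for (m in inhibition) {
      ok <- (is.numeric(m) && length(m) == 1L && m >= 0 && m <= 1) ||
        (is.list(m) && all(c("IC50", "HillSlope") %in% names(m)) &&
           m$IC50 > 0 && m$HillSlope > 0)
      if (!ok)
        stop("each inhibition entry must be a fraction in [0,1] or list(IC50, HillSlope)")
    }
  }
  structure(list(name = name, P_f = P_f, P_gly = P_gly,
                 geometry = geometry, shock_water = shock_water,
                 shock_glycerol = shock_glycerol, modality = modality,
                 noise_sd = noise_sd, bleach_rate = bleach_rate,
                 inhibition = inhibition),
            class = "generatorPreset")
}

#' @export
print.generatorPreset <- function(x, ...) {
  cat(sprintf("generatorPreset '%s': P_f = %g, P_gly = %g cm/s; %s; noise_sd = %g\n",
              x$name, x$P_f, x$P_gly, x$modality, x$noise_sd))
  invisible(x)
}

#' Built-in presets pinned to the reported study systems
#'
#' Four cell systems used throughout the package and its validation suite:
#' \describe{
#'   \item{rbc}{Human red blood cells (scattered light). Control
#'     permeabilities are typical erythrocyte magnitudes (P_f = 2e-2,
#'     P_gly = 2e-5 cm/s); the Rottlerin inhibition model uses the reported
#'     IC50s (water 22.8 uM, Hill slope 1; glycerol 6.7 uM, Hill slope 3.5).}
#'   \item{yeast_aqp1}{hAQP1-expressing yeast (carboxyfluorescein
#'     fluorescence), P_f = 3.002e-3 cm/s; glycerol leak at the empty-vector
#'     level; no Rottlerin effect.}
#'   \item{yeast_aqp3}{hAQP3-expressing yeast, P_gly = 4.54e-6 cm/s,
#'     P_f = 1.5e-3 cm/s; Rottlerin treatment modelled as fixed fractional
#'     reductions of 73% (P_gly) and 22% (P_f).}
#'   \item{yeast_empty}{Empty-vector yeast, P_f = 0.439e-3,
#'     P_gly = 0.162e-6 cm/s.}
#' }
#' Shock conditions assume 1:1 mixing with the shock solution: RBC water
#' shock 0.4 osM total, RBC glycerol shock 0.3 osM impermeant + 0.1 osM
#' glycerol; yeast shocks (1.4 + 2.1)/2 = 1.75 osM total, with the glycerol
#' shock split 0.7 impermeant + 1.05 permeant.
#'
#' @return Named list of [generatorPreset()] objects.
#' @export
aqpPresets <- function() {
  rbc_geom <- cellGeometry(6.7e-5)
  yeast_geom <- cellGeometry(6.67e-5)
  yeast_w <- shockConditions(1.4, 1.75)
  yeast_g <- shockConditions(1.4, 0.7, 1.05)
  list(
    rbc = generatorPreset(
      "rbc", P_f = 2e-2, P_gly = 2e-5, geometry = rbc_geom,
      shock_water = shockConditions(0.3, 0.4),
      shock_glycerol = shockConditions(0.3, 0.3, 0.1),
      modality = "scatter", noise_sd = 0.02, bleach_rate = 0,
      inhibition = list(P_f = list(IC50 = 22.8, HillSlope = 1.0),
                        P_gly = list(IC50 = 6.7, HillSlope = 3.5))),
    yeast_aqp1 = generatorPreset(
      "yeast_aqp1", P_f = 3.002e-3, P_gly = 0.162e-6, geometry = yeast_geom,
      shock_water = yeast_w, shock_glycerol = yeast_g,
      modality = "fluorescence", noise_sd = 0.02, bleach_rate = 1e-5),
    yeast_aqp3 = generatorPreset(
      "yeast_aqp3", P_f = 1.5e-3, P_gly = 4.54e-6, geometry = yeast_geom,
      shock_water = yeast_w, shock_glycerol = yeast_g,
      modality = "fluorescence", noise_sd = 0.02, bleach_rate = 1e-5,
      inhibition = list(P_f = 0.22, P_gly = 0.73)),
    yeast_empty = generatorPreset(
      "yeast_empty", P_f = 0.439e-3, P_gly = 0.162e-6, geometry = yeast_geom,
      shock_water = yeast_w, shock_glycerol = yeast_g,
      modality = "fluorescence", noise_sd = 0.02, bleach_rate = 1e-5)
  )
}

#' Apply a preset's inhibition model, returning the treated preset
#'
#' Scales the preset's permeabilities by `1 - y/100`, where `y` is either
#' the fixed fractional reduction (as percent `100 * fraction`) or the Hill
#' inhibition at `concentration`.
#'
#' @param preset A [generatorPreset()] with a non-NULL inhibition model.
#' @param concentration Inhibitor concentration, uM; required when the
#'   inhibition model is Hill-type.
#' @return The treated `generatorPreset` (name suffixed `_treated`), with
#'   the applied fractional reductions stored in `$applied_inhibition`.
#' @export
treatedPreset <- function(preset, concentration = NULL) {
  stopifnot(inherits(preset, "generatorPreset"))
  if (is.null(preset$inhibition)) stop("preset has no inhibition model")
  out <- preset
  applied <- list()
  for (nm in names(preset$inhibition)) {
    m <- preset$inhibition[[nm]]
    frac <- if (is.numeric(m)) {
      m
    } else {
      if (is.null(concentration))
        stop("concentration required for Hill-type inhibition of ", nm)
      hillInhibition(concentration, log10(m$IC50), m$HillSlope) / 100
    }
    out[[nm]] <- preset[[nm]] * (1 - frac)
    applied[[nm]] <- frac
  }
  out$name <- paste0(preset$name, "_treated")
  out$applied_inhibition <- applied
  out
}

# ---- config (de)serialization -------------------------------------------

.presetToList <- function(p) {
  sc <- function(s) list(osm_in_0 = s$osm_in_0,
                         osm_out_impermeant = s$osm_out_impermeant,
                         c_out_permeant = s$c_out_permeant,
                         temperature = s$temperature)
  list(name = p$name, P_f = p$P_f, P_gly = p$P_gly,
       geometry = list(V_o_over_A = p$geometry$V_o_over_A),
       shock_water = sc(p$shock_water),
       shock_glycerol = sc(p$shock_glycerol),
       modality = p$modality, noise_sd = p$noise_sd,
       bleach_rate = p$bleach_rate, inhibition = p$inhibition)
}

.presetFromList <- function(x) {
  sc <- function(s) shockConditions(s$osm_in_0, s$osm_out_impermeant,
                                    s$c_out_permeant, s$temperature)
  generatorPreset(x$name, x$P_f, x$P_gly,
                  cellGeometry(x$geometry$V_o_over_A),
                  sc(x$shock_water), sc(x$shock_glycerol),
                  x$modality, x$noise_sd, x$bleach_rate, x$inhibition)
}

#' Write / read generator presets to a YAML config
#'
#' Round-trip is exact: `readPresets(writePresets(p, f))` reconstructs
#' identical preset objects.
#'
#' @param presets Named list of [generatorPreset()] objects.
#' @param path Output YAML file.
#' @return `writePresets` returns `path` invisibly; `readPresets` returns a
#'   named list of presets.
#' @export
writePresets <- function(presets, path) {
  if (inherits(presets, "generatorPreset")) presets <- list(presets)
  yaml::write_yaml(lapply(presets, .presetToList), path,
                   precision = 15)
  invisible(path)
}

#' @rdname writePresets
#' @export
readPresets <- function(path) {
  if (!file.exists(path)) stop("preset file not found: ", path)
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, .presetFromList)
  names(out) <- vapply(out, `[[`, "", "name")
  out
}
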
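# Interchange formats and end-to-end pipeline wiring.

#' Write / read a stopped-flow trace as CSV with a JSON sidecar
#'
#' The CSV carries `time_s` and `signal` at 12 significant digits; the
#' sidecar (`<path>.json`) carries modality, shock conditions, geometry and
#' any generator ground truth, so the round-trip is lossless at that
#' precision.
#'
#' @param trace A `volumeTrace`.
#' @param path CSV file path.
#' @param sidecar Write/read the JSON sidecar (default TRUE).
#' @return `writeTraceCsv` returns `path` invisibly; `readTraceCsv` a
#'   `volumeTrace`.
#' @export
writeTraceCsv <- function(trace, path, sidecar = TRUE) {
  stopifnot(inherits(trace, "volumeTrace"))
  df <- data.frame(time_s = format(trace$time, digits = 12),
                   signal = format(trace$signal, digits = 12))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    side <- list(modality = trace$modality,
                 conditions = unclass(trace$conditions),
                 geometry = list(V_o_over_A = trace$geometry$V_o_over_A),
                 meta = trace$meta)
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname writeTraceCsv
#' @export
readTraceCsv <- function(path, sidecar = TRUE) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  names(df) <- tolower(names(df))
  req <- c("time_s", "signal")
  if (!all(req %in% names(df)))
    stop("trace CSV must have columns time_s and signal (case-insensitive)")
  time <- as.numeric(df$time_s)
  signal <- as.numeric(df$signal)
  bad <- which(!is.finite(time) | !is.finite(signal))
  if (length(bad))
    stop("malformed trace row(s) at line(s) ",
         paste(bad + 1L, collapse = ", "))
  if (any(diff(time) <= 0)) {
    ln <- which(diff(time) <= 0)[1] + 2L
    stop("time column not strictly increasing at line ", ln)
  }
  extra <- setdiff(names(df), req)
  modality <- "scatter"
  conditions <- NULL; geometry <- NULL; meta <- list()
  sp <- paste0(path, ".json")
  if (sidecar && file.exists(sp)) {
    side <- jsonlite::read_json(sp, simplifyVector = TRUE)
    modality <- side$modality
    conditions <- shockConditions(side$conditions$osm_in_0,
                                  side$conditions$osm_out_impermeant,
                                  side$conditions$c_out_permeant,
                                  side$conditions$temperature)
    geometry <- cellGeometry(side$geometry$V_o_over_A)
    meta <- side$meta
  }
  if (length(extra)) meta$extra_columns <- df[extra]
  .newVolumeTrace(time, signal, modality, conditions, geometry, meta)
}

#' Write analysis records to JSON or TSV
#'
#' JSON (`.json`) for nested records, TSV otherwise. Numbers are written
#' in full precision; every file gets the producing config digest when one
#' is supplied.
#'
#' @param records A list (JSON) or data.frame (either format).
#' @param path Output file; format chosen by extension.
#' @param config_digest Optional digest string stored alongside.
#' @return `path`, invisibly.
#' @export
writeResults <- function(records, path, config_digest = NULL) {
  if (grepl("\\.json$", path)) {
    if (!is.null(config_digest))
      records <- c(list(config_digest = config_digest),
                   if (is.data.frame(records)) list(records = records)
                   else records)
    jsonlite::write_json(records, path, auto_unbox = TRUE, digits = NA,
                         null = "null", dataframe = "rows")
  } else {
    if (!is.data.frame(records)) records <- as.data.frame(records)
    if (!is.null(config_digest)) {
      con <- file(path, "w")
      writeLines(paste0("# config_digest: ", config_digest), con)
      utils::write.table(records, con, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      close(con)
    } else {
      utils::write.table(records, path, sep = "\t", row.names = FALSE,
                         quote = FALSE)
    }
  }
  invisible(path)
}

#' Write a free-energy landscape as a gridded CSV
#'
#' One row per bin: `d1_lo, d1_hi, d2_lo, d2_hi, dG_kJmol, masked`.
#'
#' @param grid A `fesGrid`.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
writeFesCsv <- function(grid, path) {
  stopifnot(inherits(grid, "fesGrid"))
  nb1 <- nrow(grid$dG); nb2 <- ncol(grid$dG)
  idx <- expand.grid(i = seq_len(nb1), j = seq_len(nb2))
  df <- data.frame(d1_lo = grid$d1_edges[idx$i],
                   d1_hi = grid$d1_edges[idx$i + 1],
                   d2_lo = grid$d2_edges[idx$j],
                   d2_hi = grid$d2_edges[idx$j + 1],
                   dG_kJmol = grid$dG[cbind(idx$i, idx$j)],
                   masked = is.na(grid$dG[cbind(idx$i, idx$j)]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read multi-frame coordinates as a multi-model PDB
#'
#' Frames are wrapped in `MODEL`/`ENDMDL` records; per-model ATOM
#' formatting is delegated to bio3d, and reading uses
#' `bio3d::read.pdb(multi = TRUE)`.
#'
#' @param frames An `mdFrames` object.
#' @param path PDB file path.
#' @return `writePdbFrames` returns `path` invisibly; `readPdbFrames` an
#'   `mdFrames`.
#' @export
writePdbFrames <- function(frames, path) {
  stopifnot(inherits(frames, "mdFrames"))
  at <- frames$atoms
  if (anyDuplicated(at$serial)) stop("overlapping atom serial numbers")
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  lines <- character(0)
  for (f in seq_len(nrow(frames$xyz))) {
    bio3d::write.pdb(file = tmp, xyz = frames$xyz[f, ],
                     eleno = at$serial, elety = at$elety, resid = at$resid,
                     chain = at$chain, resno = at$resno)
    body <- grep("^(ATOM|HETATM)", readLines(tmp), value = TRUE)
    lines <- c(lines, sprintf("MODEL     %4d", f), body, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' @rdname writePdbFrames
#' @export
readPdbFrames <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  atoms <- data.frame(serial = pdb$atom$eleno, elety = pdb$atom$elety,
                      resid = pdb$atom$resid, chain = pdb$atom$chain,
                      resno = pdb$atom$resno, stringsAsFactors = FALSE)
  structure(list(atoms = atoms, xyz = unclass(xyz),
                 times_ns = as.numeric(seq_len(nrow(xyz)))),
            class = "mdFrames")
}

#' Read a run configuration (YAML or JSON)
#'
#' @param path Config file; `.json` is parsed as JSON, anything else as
#'   YAML.
#' @return Named list.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                   simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' Fit one trace through to a permeability coefficient
#'
#' Convenience wrapper for the inverse chain on a single trace: optional
#' bleach correction (fluorescence, when a baseline is supplied), rate
#' fitting ([fitShrinkageRate()] for water, [fitReswellingRate()] for
#' glycerol), then conversion to a permeability.
#'
#' @param trace A `volumeTrace`.
#' @param kind `"water"` or `"glycerol"`.
#' @param baseline Optional isotonic baseline `volumeTrace` for bleach
#'   correction.
#' @return A `permeabilityResult`.
#' @export
tracePermeability <- function(trace, kind = c("water", "glycerol"),
                              baseline = NULL) {
  kind <- match.arg(kind)
  if (!is.null(baseline) && trace$modality == "fluorescence")
    trace <- correctBleaching(trace, baseline)
  if (kind == "water")
    waterPermeability(fitShrinkageRate(trace), trace$geometry,
                      trace$conditions)
  else
    glycerolPermeability(fitReswellingRate(trace), trace$geometry)
}

#' Run the dose--response pipeline on synthetic traces
#'
#' The full inverse chain at one go: generate a seeded dose--response trace
#' set, fit every trace (shrinkage or reswelling rate), convert rates to
#' permeabilities, compute percent inhibition per concentration from the
#' mean control and treated permeabilities, and fit the Hill model. Traces
#' with no detectable post-shock kinetics (possible at near-complete
#' inhibition) are recorded as permeability 0, i.e. below detection.
#'
#' @param preset A [generatorPreset()] with a Hill inhibition entry.
#' @param concentrations Inhibitor concentrations, uM.
#' @param replicates Traces per arm per concentration.
#' @param seed Master seed.
#' @param kind `"glycerol"` or `"water"`.
#' @param duration,n_points Trace sampling (defaults as in
#'   [generateDoseResponseSet()]).
#' @return `list(points, fit, truth)`: per-concentration inhibition table,
#'   the [fitIC50()] result, and the generator truth (IC50, HillSlope).
#' @export
doseResponsePipeline <- function(preset, concentrations, replicates = 5,
                                 seed = 1, kind = c("glycerol", "water"),
                                 duration = NULL, n_points = 500) {
  kind <- match.arg(kind)
  drset <- generateDoseResponseSet(preset, concentrations, replicates,
                                   seed, kind, duration, n_points)
  baseline <- if (preset$modality == "fluorescence") {
    dur <- drset[[1]]$control[[1]]$time
    generateBaselineTrace(preset, max(dur), length(dur),
                          seed = attr(drset, "seed"))
  }
  fitP <- function(tr) {
    p <- tryCatch(
      tracePermeability(tr, kind, baseline),
      error = function(e) {
        if (grepl("no signal|not biphasic", conditionMessage(e))) NULL
        else stop(e)
      })
    if (is.null(p)) 0 else p$P
  }
  points <- do.call(rbind, lapply(drset, function(el) {
    pc <- mean(vapply(el$control, fitP, 0))
    pt <- mean(vapply(el$treated, fitP, 0))
    data.frame(concentration = el$concentration,
               inhibition = percentInhibition(pc, pt),
               true_inhibition = el$true_inhibition)
  }))
  pkey <- if (kind == "glycerol") "P_gly" else "P_f"
  truth <- preset$inhibition[[pkey]]
  list(points = points, fit = fitIC50(points), truth = truth)
}

#' Closed-loop yeast permeability recovery experiment
#'
#' Reproduces the heterologous-expression assay panel on synthetic data:
#' water and glycerol traces for hAQP1-, hAQP3- and empty-vector yeast
#' (plus the Rottlerin-treated hAQP3 variant), fitted back to
#' permeabilities, with the derived comparative statistics. Acquisition
#' protocol: 1000 samples per trace; glycerol traces recorded for
#' `min(20/k_g, 1500)` s (full reswelling plateau within the practical
#' acquisition cap), water traces for `8/k_w` s; fluorescence traces are
#' bleach-corrected against a matched isotonic baseline before fitting.
#' Per-trace seeds derive deterministically from `seed`.
#'
#' @param seed Master seed.
#' @param replicates Traces per condition (default 7, the upper end of the
#'   5--7 replicates typical for stopped-flow assays).
#' @return List with mean fitted permeabilities (`P_f_aqp1`, `P_f_aqp3`,
#'   `P_f_aqp3_treated`, `P_gly_aqp3`, `P_gly_aqp3_treated`,
#'   `P_gly_empty`), `fold_gly` (hAQP3 vs empty-vector P_gly),
#'   `inhibition_gly` and `inhibition_water` (treated vs control hAQP3, %).
#' @export
runYeastAssays <- function(seed = 1, replicates = 7) {
  p <- aqpPresets()
  trt <- treatedPreset(p$yeast_aqp3)
  np <- 1000L
  seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 1L, 6L * replicates + 6L))
  si <- 0L
  nxt <- function() { si <<- si + 1L; seeds[si] }
  gly_dur <- function(pr)
    min(20 / linearizedRate(pr$P_gly, pr$geometry, kind = "glycerol"), 1500)
  wat_dur <- function(pr)
    8 / linearizedRate(pr$P_f, pr$geometry, pr$shock_water, "water")

  meanP <- function(pr, kind) {
    dur <- if (kind == "glycerol") gly_dur(pr) else wat_dur(pr)
    gen <- if (kind == "glycerol") generateGlycerolTrace else generateWaterTrace
    traces <- lapply(seq_len(replicates), function(i)
      gen(pr, dur, np, seed = nxt()))
    baseline <- if (pr$modality == "fluorescence")
      generateBaselineTrace(pr, dur, np, seed = nxt())
    mean(vapply(traces, function(tr)
      tracePermeability(tr, kind, baseline)$P, 0))
  }

  out <- list(
    P_f_aqp1 = meanP(p$yeast_aqp1, "water"),
    P_f_aqp3 = meanP(p$yeast_aqp3, "water"),
    P_f_aqp3_treated = meanP(trt, "water"),
    P_gly_aqp3 = meanP(p$yeast_aqp3, "glycerol"),
    P_gly_aqp3_treated = meanP(trt, "glycerol"),
    P_gly_empty = meanP(p$yeast_empty, "glycerol"))
  out$fold_gly <- foldChange(out$P_gly_aqp3, out$P_gly_empty)
  out$inhibition_gly <- percentInhibition(out$P_gly_aqp3,
                                          out$P_gly_aqp3_treated)
  out$inhibition_water <- percentInhibition(out$P_f_aqp3,
                                            out$P_f_aqp3_treated)
  out
}

#' Run a configured end-to-end analysis
#'
#' Executes the stages named in `config$stages` and writes all results plus
#' a manifest (package version, seeds, config digest, output digests) into
#' `out_dir`. Supported stages:
#' \describe{
#'   \item{dose_response}{fields: `preset` (built-in name or preset file),
#'     `kind`, `concentrations`, `replicates`, `seed`.}
#'   \item{landscape}{fields: `mixture` (list of weight/mean/cov), `n`,
#'     `seed`, optional `n_bins`, `depth_cutoff`, `d1_min`, `d2_min`,
#'     `n_per_basin`.}
#' }
#'
#' @param config A list or path to a YAML/JSON config file.
#' @param out_dir Output directory (created if needed).
#' @return Named list of stage results, invisibly; files in `out_dir`.
#' @export
runPipeline <- function(config, out_dir = "aquaflux_run") {
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    config <- readConfig(config)
  }
  if (is.null(config$stages)) stop("config must name its stages")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  digest <- if (!is.null(config_path)) unname(tools::md5sum(config_path))
  else unname(tools::md5sum(.writeTempConfig(config)))

  results <- list()
  for (stage in config$stages) {
    sc <- config[[stage]]
    if (is.null(sc)) stop("stage '", stage, "' has no config block")
    results[[stage]] <- switch(
      stage,
      dose_response = .stageDoseResponse(sc, out_dir, digest),
      landscape = .stageLandscape(sc, out_dir, digest),
      stop("unknown stage: ", stage))
  }
  manifest <- list(
    package = "aquaflux",
    version = as.character(utils::packageVersion("aquaflux")),
    config_digest = digest,
    stages = config$stages,
    outputs = as.list(tools::md5sum(list.files(out_dir, full.names = TRUE))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}

.writeTempConfig <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, tmp, precision = 15)
  tmp
}

.stageDoseResponse <- function(sc, out_dir, digest) {
  preset <- if (file.exists(sc$preset %||% "")) readPresets(sc$preset)[[1]]
  else aqpPresets()[[sc$preset]]
  if (is.null(preset)) stop("unknown preset: ", sc$preset)
  res <- doseResponsePipeline(preset, unlist(sc$concentrations),
                              sc$replicates %||% 5, sc$seed %||% 1,
                              sc$kind %||% "glycerol")
  writeResults(res$points, file.path(out_dir, "inhibition.tsv"), digest)
  writeResults(list(IC50 = res$fit$IC50, LogIC50 = res$fit$LogIC50,
                    HillSlope = res$fit$HillSlope,
                    ci_95 = res$fit$ci,
                    residual_rms = res$fit$residual_rms),
               file.path(out_dir, "ic50.json"), digest)
  res
}

.stageLandscape <- function(sc, out_dir, digest) {
  mixture <- lapply(sc$mixture, function(m)
    list(weight = m$weight, mean = unlist(m$mean), cov = unlist(m$cov)))
  samples <- generateCVSamples(mixture, sc$n %||% 10000, sc$seed %||% 1)
  grid <- freeEnergyLandscape(samples,
                              n_bins = sc$n_bins %||% c(50, 50))
  basins <- findBasins(grid, sc$depth_cutoff %||% 2.5)
  selection <- selectBindingReady(samples, basins,
                                  d1_min = sc$d1_min %||% 1.9,
                                  d2_min = sc$d2_min %||% 1.19,
                                  n_per_basin = sc$n_per_basin %||% 5,
                                  seed = sc$seed %||% 1)
  writeFesCsv(grid, file.path(out_dir, "fes.csv"))
  writeResults(lapply(basins, function(b)
    list(label = b$label, min_dG = b$min_dG,
         d1 = unname(b$min_location["d1"]),
         d2 = unname(b$min_location["d2"]))),
    file.path(out_dir, "basins.json"), digest)
  writeResults(selection, file.path(out_dir, "conformers.tsv"), digest)
  list(grid = grid, basins = basins, selection = selection)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
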
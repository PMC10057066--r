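# MD post-processing: loop-distance collective variables, 2D free-energy
# landscape, basin detection, binding-ready conformer selection, and
# ligand-residue contact profiling.

#' Define a pair of extracellular loops for a distance collective variable
#'
#' @param loop_a,loop_b Inclusive residue-number ranges `c(first, last)`.
#'   The two ranges must be non-empty and non-overlapping.
#' @return A `loopDefinition`.
#' @examples
#' d1 <- loopDefinition(c(52, 54), c(209, 211))
#' d2 <- loopDefinition(c(144, 151), c(234, 236))
#' @export
loopDefinition <- function(loop_a, loop_b) {
  stopifnot(length(loop_a) == 2, length(loop_b) == 2)
  if (loop_a[1] > loop_a[2] || loop_b[1] > loop_b[2])
    stop("residue ranges must be non-empty (first <= last)")
  if (max(loop_a[1], loop_b[1]) <= min(loop_a[2], loop_b[2]))
    stop("loop residue ranges must not overlap")
  structure(list(loop_a = as.integer(loop_a), loop_b = as.integer(loop_b)),
            class = "loopDefinition")
}

# xyz row (3N) -> n_atoms x 3 matrix
.frameCoords <- function(xyz_row) matrix(xyz_row, ncol = 3, byrow = TRUE)

.loopCentroid <- function(coords, atoms, chain, rng, method) {
  sel <- which(atoms$chain == chain & atoms$elety == "CA" &
                 atoms$resno >= rng[1] & atoms$resno <= rng[2])
  present <- unique(atoms$resno[sel])
  missing <- setdiff(seq(rng[1], rng[2]), present)
  if (length(missing))
    stop("missing CA atom(s) for residue(s) ",
         paste(missing, collapse = ", "), " in chain ", chain)
  coords[sel, , drop = FALSE]
}

#' Inter-loop distance collective variables from a trajectory
#'
#' For every frame and monomer (chain), computes the Euclidean distance
#' between the C-alpha centers of geometry of each loop pair, in nm
#' (coordinates are Angstrom as read from PDB). With
#' `method = "min"`, the minimum C-alpha inter-atom distance is used
#' instead of centroids.
#'
#' @param frames An `mdFrames` object ([readPdbFrames()] or
#'   [generateToyComplex()]).
#' @param def_d1,def_d2 [loopDefinition()]s for the two distances.
#' @param chains Chains to treat as monomers; default: all chains that
#'   contain CA atoms.
#' @param replicate Replicate id to tag samples with.
#' @param method `"cog"` (center of geometry, default) or `"min"`.
#' @return A `cvSamples` data.frame (`frame`, `monomer`, `replicate`,
#'   `time_ns`, `d1`, `d2`).
#' @export
computeLoopDistances <- function(frames, def_d1, def_d2, chains = NULL,
                                 replicate = 1L,
                                 method = c("cog", "min")) {
  method <- match.arg(method)
  stopifnot(inherits(frames, "mdFrames"),
            inherits(def_d1, "loopDefinition"),
            inherits(def_d2, "loopDefinition"))
  atoms <- frames$atoms
  if (is.null(chains))
    chains <- sort(unique(atoms$chain[atoms$elety == "CA"]))
  n_frames <- nrow(frames$xyz)
  dist_for <- function(coords, def, chain) {
    ca <- .loopCentroid(coords, atoms, chain, def$loop_a, method)
    cb <- .loopCentroid(coords, atoms, chain, def$loop_b, method)
    if (method == "cog") {
      sqrt(sum((colMeans(ca) - colMeans(cb))^2)) / 10
    } else {
      min(sqrt(outer(rowSums(ca^2), rowSums(cb^2), "+") -
                 2 * ca %*% t(cb))) / 10
    }
  }
  rows <- vector("list", n_frames * length(chains))
  i <- 0L
  for (f in seq_len(n_frames)) {
    coords <- .frameCoords(frames$xyz[f, ])
    for (ch in chains) {
      i <- i + 1L
      rows[[i]] <- data.frame(
        frame = f, monomer = ch, replicate = replicate,
        time_ns = frames$times_ns[f],
        d1 = dist_for(coords, def_d1, ch),
        d2 = dist_for(coords, def_d2, ch))
    }
  }
  structure(do.call(rbind, rows), class = c("cvSamples", "data.frame"))
}

#' Two-dimensional free-energy landscape over (d1, d2)
#'
#' Bins the samples on a regular grid (range padded by `pad` on each side)
#' and converts counts to free energies,
#' \eqn{\Delta G = -k_B T \ln(count/count_{max})} (kJ/mol), so the most
#' populated bin is exactly 0 and every occupied bin is >= 0. Empty bins
#' are masked (`NA`), never zero.
#'
#' @param samples A `cvSamples` data.frame (>= 100 samples).
#' @param n_bins Bins per axis, length 1 or 2 (>= 10 each).
#' @param temperature Temperature for \eqn{k_B T}, K.
#' @param pad Fractional range padding per side.
#' @return A `fesGrid`: `list(d1_edges, d2_edges, counts, dG, temperature)`.
#' @export
freeEnergyLandscape <- function(samples, n_bins = c(50, 50),
                                temperature = 298.15, pad = 0.02) {
  stopifnot(is.data.frame(samples), all(c("d1", "d2") %in% names(samples)))
  if (nrow(samples) < 100) stop("need at least 100 samples")
  n_bins <- rep(as.integer(n_bins), length.out = 2)
  if (any(n_bins < 10)) stop("need at least 10 bins per axis")
  edges <- function(x, nb) {
    r <- range(x); w <- diff(r)
    if (w == 0) w <- max(abs(r[1]), 1) * 1e-6
    seq(r[1] - pad * w, r[2] + pad * w, length.out = nb + 1)
  }
  e1 <- edges(samples$d1, n_bins[1])
  e2 <- edges(samples$d2, n_bins[2])
  i1 <- .bincode2(samples$d1, e1)
  i2 <- .bincode2(samples$d2, e2)
  counts <- matrix(0L, n_bins[1], n_bins[2])
  for (k in seq_along(i1))
    counts[i1[k], i2[k]] <- counts[i1[k], i2[k]] + 1L
  if (sum(counts > 0) == 1)
    warning("degenerate landscape: all samples fall in a single bin")
  kT <- .KB_KJMOL * temperature
  dG <- matrix(NA_real_, n_bins[1], n_bins[2])
  occ <- counts > 0
  dG[occ] <- kT * (log(max(counts)) - log(counts[occ]))
  structure(list(d1_edges = e1, d2_edges = e2, counts = counts, dG = dG,
                 temperature = temperature),
            class = "fesGrid")
}

.bincode2 <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  pmin(pmax(i, 1L), length(edges) - 1L)
}

#' @export
print.fesGrid <- function(x, ...) {
  cat(sprintf("fesGrid: %d x %d bins, %d occupied, T = %g K, max dG = %.3g kJ/mol\n",
              nrow(x$dG), ncol(x$dG), sum(!is.na(x$dG)), x$temperature,
              max(x$dG, na.rm = TRUE)))
  invisible(x)
}

#' Detect basins of a free-energy landscape
#'
#' Basins are the connected components (4-connectivity) of the occupied
#' bins with \eqn{\Delta G \le} `depth_cutoff`. Each component is reduced
#' to its minimum bin; labels are assigned in ascending order of minimum
#' free energy, ties broken lexicographically by the (d1, d2) minimum
#' location.
#'
#' Because the landscape is a finite-sample histogram, Poisson shot noise
#' at the sublevel boundary can detach isolated bins from a populated
#' basin; components smaller than `min_bins` bins are therefore discarded
#' as noise. When *every* component is smaller than `min_bins` (e.g. a
#' cutoff so tight that each basin is a single bin) the filter is skipped,
#' so the tight-cutoff limit still reports each minimum as its own basin.
#'
#' @param grid A [freeEnergyLandscape()] result.
#' @param depth_cutoff Sublevel cutoff, kJ/mol (default 2.5, about 1 kT at
#'   298.15 K).
#' @param min_bins Minimum component size treated as a real basin
#'   (default 3).
#' @return A `basinSet`: list of basins, each `list(label, bins,
#'   min_index, min_location, min_dG, depth)`; grid edges attached as
#'   attributes for downstream sample lookup. Empty list when no bin lies
#'   below the cutoff.
#' @export
findBasins <- function(grid, depth_cutoff = 2.5, min_bins = 3) {
  stopifnot(inherits(grid, "fesGrid"))
  mask <- !is.na(grid$dG) & grid$dG <= depth_cutoff
  comp <- .connectedComponents(mask)
  n_comp <- max(comp, 0L)
  if (n_comp == 0L)
    return(structure(list(), class = "basinSet",
                     d1_edges = grid$d1_edges, d2_edges = grid$d2_edges))
  sizes <- tabulate(comp[comp > 0L], n_comp)
  keep <- if (any(sizes >= min_bins)) which(sizes >= min_bins)
  else seq_len(n_comp)
  mid <- function(e, i) (e[i] + e[i + 1]) / 2
  basins <- lapply(keep, function(cc) {
    bins <- which(comp == cc, arr.ind = TRUE)
    g <- grid$dG[bins]
    cand <- which(g == min(g))
    locs <- cbind(mid(grid$d1_edges, bins[cand, 1]),
                  mid(grid$d2_edges, bins[cand, 2]))
    pick <- cand[order(locs[, 1], locs[, 2])[1]]
    list(bins = bins,
         min_index = bins[pick, , drop = TRUE],
         min_location = c(d1 = mid(grid$d1_edges, bins[pick, 1]),
                          d2 = mid(grid$d2_edges, bins[pick, 2])),
         min_dG = g[pick],
         depth = depth_cutoff - g[pick])
  })
  ord <- order(vapply(basins, `[[`, 0, "min_dG"),
               vapply(basins, function(b) b$min_location["d1"], 0),
               vapply(basins, function(b) b$min_location["d2"], 0))
  basins <- basins[ord]
  for (i in seq_along(basins)) basins[[i]]$label <- i
  structure(basins, class = "basinSet",
            d1_edges = grid$d1_edges, d2_edges = grid$d2_edges)
}

#' @export
print.basinSet <- function(x, ...) {
  cat(sprintf("basinSet: %d basin(s)\n", length(x)))
  for (b in x)
    cat(sprintf("  basin %d: min dG = %.3g kJ/mol at (d1 = %.3g, d2 = %.3g) nm, %d bins\n",
                b$label, b$min_dG, b$min_location["d1"],
                b$min_location["d2"], nrow(b$bins)))
  invisible(x)
}

# 4-connectivity flood fill on a logical matrix; returns integer labels
# (0 = background).
.connectedComponents <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- ((p - 1L) %% nr) + 1L
      j <- ((p - 1L) %/% nr) + 1L
      for (q in c(if (i > 1L) p - 1L, if (i < nr) p + 1L,
                  if (j > 1L) p - nr, if (j < nc) p + nr)) {
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          stack <- c(stack, q)
        }
      }
    }
  }
  lab
}

#' Select binding-ready conformers from qualifying basins
#'
#' Keeps basins whose minimum satisfies `d1 > d1_min` and `d2 > d2_min`
#' (defaults 1.9 and 1.19 nm: loops open enough for ligand access to the
#' pore vestibule), then draws `n_per_basin` distinct samples uniformly
#' (seeded) from each basin's member samples that themselves pass the
#' thresholds.
#'
#' @param samples The `cvSamples` the landscape was computed from.
#' @param basins A [findBasins()] result on those samples.
#' @param d1_min,d2_min Threshold distances, nm (strict inequality).
#' @param n_per_basin Conformations drawn per qualifying basin.
#' @param seed Integer seed for the within-basin sampling.
#' @return Data frame of selected conformers: `basin`, `frame`, `monomer`,
#'   `replicate`, `d1`, `d2`.
#' @export
selectBindingReady <- function(samples, basins, d1_min = 1.9,
                               d2_min = 1.19, n_per_basin = 5, seed = 1) {
  stopifnot(inherits(basins, "basinSet"), is.data.frame(samples))
  e1 <- attr(basins, "d1_edges"); e2 <- attr(basins, "d2_edges")
  i1 <- .bincode2(samples$d1, e1)
  i2 <- .bincode2(samples$d2, e2)
  qualifying <- Filter(function(b)
    b$min_location["d1"] > d1_min && b$min_location["d2"] > d2_min, basins)
  if (!length(qualifying))
    return(samples[0, c("frame", "monomer", "replicate", "d1", "d2")])
  sel <- withr::with_seed(seed, {
    lapply(qualifying, function(b) {
      inbasin <- paste(i1, i2) %in% paste(b$bins[, 1], b$bins[, 2])
      member <- which(inbasin & samples$d1 > d1_min & samples$d2 > d2_min)
      if (length(member) < n_per_basin)
        stop("basin ", b$label, " has only ", length(member),
             " qualifying samples (need ", n_per_basin, ")")
      take <- member[sample.int(length(member), n_per_basin)]
      cbind(basin = b$label,
            samples[take, c("frame", "monomer", "replicate", "d1", "d2")])
    })
  })
  out <- do.call(rbind, sel)
  rownames(out) <- NULL
  out
}

#' Per-residue ligand contact profile over a trajectory window
#'
#' For every frame whose time lies in `window` (inclusive), counts
#' ligand-atom/protein-atom pairs closer than `cutoff` (strict inequality)
#' and aggregates the counts per protein residue; the profile is the mean
#' count per frame, ranked in decreasing order. Every protein residue in
#' the structure appears, including those with zero contacts.
#'
#' @param frames An `mdFrames` object.
#' @param ligand_resid Residue name identifying ligand atoms.
#' @param window `c(t_start, t_end)` in ns; default: all frames.
#' @param cutoff Contact distance cutoff, nm.
#' @return A `contactProfile` data.frame (`chain`, `resno`, `resid`,
#'   `mean_contacts`), sorted by decreasing mean contacts; window and
#'   cutoff stored as attributes.
#' @export
contactCounts <- function(frames, ligand_resid = "LIG", window = NULL,
                          cutoff = 0.4) {
  stopifnot(inherits(frames, "mdFrames"))
  atoms <- frames$atoms
  lig <- which(atoms$resid == ligand_resid)
  if (!length(lig)) stop("no ligand atoms with residue name ", ligand_resid)
  prot <- which(atoms$resid != ligand_resid)
  if (is.null(window)) window <- range(frames$times_ns)
  fsel <- which(frames$times_ns >= window[1] & frames$times_ns <= window[2])
  if (!length(fsel)) stop("empty window: no frames in [",
                          window[1], ", ", window[2], "] ns")
  cutA <- cutoff * 10  # nm -> Angstrom
  key <- paste(atoms$chain[prot], atoms$resno[prot])
  ukey <- unique(key)
  acc <- stats::setNames(numeric(length(ukey)), ukey)
  for (f in fsel) {
    coords <- .frameCoords(frames$xyz[f, ])
    lc <- coords[lig, , drop = FALSE]
    pc <- coords[prot, , drop = FALSE]
    d2 <- outer(rowSums(lc^2), rowSums(pc^2), "+") - 2 * lc %*% t(pc)
    # strict inequality; 1e-6 A^2 guard absorbs round-off so a pair at
    # exactly the cutoff is never counted (PDB precision is 1e-3 A)
    hit <- colSums(d2 < cutA^2 - 1e-6)
    ct <- tapply(hit, key, sum)
    acc[names(ct)] <- acc[names(ct)] + ct
  }
  first <- match(ukey, key)
  out <- data.frame(chain = atoms$chain[prot][first],
                    resno = atoms$resno[prot][first],
                    resid = atoms$resid[prot][first],
                    mean_contacts = unname(acc[ukey]) / length(fsel))
  out <- out[order(-out$mean_contacts, out$chain, out$resno), ]
  rownames(out) <- NULL
  structure(out, class = c("contactProfile", "data.frame"),
            window = window, cutoff = cutoff, n_frames = length(fsel))
}
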
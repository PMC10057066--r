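# Shared fixtures for the suite. Everything is built in code; no files.

yeast_geom <- cellGeometry(6.67e-5)
yeast_water_shock <- shockConditions(1.4, 1.75)

# preset matching the printed hAQP1-yeast water / hAQP3-yeast glycerol
# permeabilities, scatter modality so no bleach enters unless wanted
noiselessPreset <- function(P_f = 3.002e-3, P_gly = 4.54e-6,
                            modality = "scatter", noise_sd = 0,
                            bleach_rate = 0, inhibition = NULL) {
  generatorPreset("fixture", P_f, P_gly, yeast_geom,
                  shock_water = yeast_water_shock,
                  shock_glycerol = shockConditions(1.4, 0.7, 1.05),
                  modality = modality, noise_sd = noise_sd,
                  bleach_rate = bleach_rate, inhibition = inhibition)
}

# well-separated 3-component mixture in the binding-ready region
threeBasinMixture <- function(sd = 0.05) {
  list(list(weight = 1/3, mean = c(2.0, 1.3), cov = sd^2),
       list(weight = 1/3, mean = c(2.4, 1.6), cov = sd^2),
       list(weight = 1/3, mean = c(2.8, 1.3), cov = sd^2))
}

# hand-built mdFrames with explicit coordinates (nm -> Angstrom)
makeFrames <- function(coords_nm_list, atoms) {
  xyz <- do.call(rbind, lapply(coords_nm_list, function(m)
    as.numeric(t(m)) * 10))
  structure(list(atoms = atoms, xyz = xyz,
                 times_ns = as.numeric(seq_along(coords_nm_list))),
            class = "mdFrames")
}

caAtoms <- function(resno, chain = "A", resid = "ALA", elety = "CA") {
  n <- length(resno)
  data.frame(serial = seq_len(n), elety = rep(elety, length.out = n),
             resid = rep(resid, length.out = n),
             chain = rep(chain, length.out = n),
             resno = resno, stringsAsFactors = FALSE)
}
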
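# Internal unit conventions: lengths cm, volumes cm^3, time s,
# permeabilities cm s^-1. Osmolarities are accepted in osM (osmol/L) and
# converted to mol cm^-3 where they enter a flux law.

# molar volume of water, cm^3 mol^-1
.VW <- 18

# osM (= mol/L for ideal solutes) -> mol cm^-3
.OSM_TO_MOLCM3 <- 1e-3

# Boltzmann/gas constant in kJ mol^-1 K^-1 (molar k_B)
.KB_KJMOL <- 0.008314462618

.osm_to_molcm3 <- function(x) x * .OSM_TO_MOLCM3
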
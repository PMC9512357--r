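# Photon interaction and electron stopping-power data for the simplified
# transport engine.  Materials: 1 water, 2 air, 3 lung (tissue at low
# density), 4 bone.  Compton attenuation is computed in closed form from the
# Klein-Nishina total cross section times the electron density per gram;
# photoelectric and pair-production coefficients are compact knot tables /
# power laws at the few-percent accuracy appropriate to a declared simplified
# engine (Rayleigh scattering is omitted).  All mass coefficients in cm^2/g,
# stopping powers in MeV cm^2/g, energies in MeV.

.MATERIALS <- c("water", "air", "lung", "bone")

# electron densities per gram (electrons/g)
.NE_PER_G <- c(water = 3.3428e23, air = 3.0061e23, lung = 3.3419e23, bone = 3.1920e23)

# photoelectric: tau(E) = peScale * 0.025 * (0.05 / E)^3  (cm^2/g, water ref)
.PE_SCALE <- c(water = 1.0, air = 1.06, lung = 1.0, bone = 4.5)

# pair production knots for water (cm^2/g), linear interpolation in E
.PAIR_E   <- c(1.022, 1.25, 1.50, 2.00, 2.50, 3.00, 4.00, 5.00, 6.00, 6.50)
.PAIR_MU  <- c(0, 6.0e-5, 1.6e-4, 4.0e-4, 7.3e-4, 1.1e-3, 1.84e-3, 2.50e-3, 3.10e-3, 3.35e-3)
.PAIR_SCALE <- c(water = 1.0, air = 1.0, lung = 1.0, bone = 1.35)

# electron collision stopping power for water (MeV cm^2/g); other materials
# scaled by their electron density per gram
.ESTOP_E <- c(0.01, 0.02, 0.05, 0.10, 0.20, 0.30, 0.40, 0.50, 0.70,
              1.00, 1.50, 2.00, 3.00, 4.00, 5.00, 6.00, 6.50)
.ESTOP_S <- c(22.56, 13.17, 6.603, 4.115, 2.793, 2.355, 2.148, 2.034, 1.916,
              1.849, 1.822, 1.824, 1.846, 1.870, 1.892, 1.911, 1.920)

# radiation lengths (g/cm^2) for the Highland small-angle scattering model
.X0 <- c(water = 36.08, air = 36.62, lung = 36.10, bone = 17.50)

# Klein-Nishina total cross section per electron (cm^2) at photon energy E (MeV)
.kleinNishinaTotal <- function(E) {
  k <- E / 0.51099895
  re2 <- 7.94078e-26   # classical electron radius squared, cm^2
  2 * pi * re2 * (
    (1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k) +
    log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2)
}

# Mass attenuation components for one material on an energy vector.
.muComponents <- function(E, material) {
  compton <- .NE_PER_G[[material]] * .kleinNishinaTotal(E)
  pe <- .PE_SCALE[[material]] * 0.025 * (0.05 / E)^3
  pair <- .PAIR_SCALE[[material]] *
    approx(.PAIR_E, .PAIR_MU, xout = pmin(pmax(E, .PAIR_E[1]), max(.PAIR_E)),
           rule = 2)$y
  pair[E < 1.022] <- 0
  cbind(compton = compton, pe = pe, pair = pair)
}

# Build the table bundle consumed by the C++ engine: log-spaced energy grid
# covering the transport range, per-material total mass attenuation and
# interaction branch fractions, stopping powers, radiation lengths.
.physicsTables <- function(nE = 120, eMin = 0.05, eMax = 6.5) {
  E <- exp(seq(log(eMin), log(eMax), length.out = nE))
  nm <- length(.MATERIALS)
  muTot <- fPE <- fPair <- stopPow <- matrix(0, nE, nm)
  for (m in seq_len(nm)) {
    comp <- .muComponents(E, .MATERIALS[m])
    tot <- rowSums(comp)
    muTot[, m] <- tot
    fPE[, m]   <- comp[, "pe"] / tot
    fPair[, m] <- comp[, "pair"] / tot
    scale <- .NE_PER_G[[m]] / .NE_PER_G[["water"]]
    stopPow[, m] <- scale * approx(.ESTOP_E, .ESTOP_S, xout = pmin(E, max(.ESTOP_E)),
                                   rule = 2)$y
  }
  list(energy = E, muTot = muTot, fPE = fPE, fPair = fPair,
       stopPow = stopPow, X0 = unname(.X0), materials = .MATERIALS)
}

.pkgCache <- new.env(parent = emptyenv())

.getPhysics <- function() {
  if (is.null(.pkgCache$physics)) .pkgCache$physics <- .physicsTables()
  .pkgCache$physics
}

#' Total mass attenuation coefficient
#'
#' Interpolated total photon mass attenuation coefficient of the packaged
#' cross-section tables (Compton from the Klein-Nishina closed form,
#' photoelectric, pair production; no Rayleigh).
#'
#' @param energy photon energy (MeV), in the transport range 0.05-6.5.
#' @param material `"water"`, `"air"`, `"lung"` or `"bone"`.
#' @return mass attenuation coefficient (cm^2/g).
#' @export
muTotal <- function(energy, material = "water") {
  ph <- .getPhysics()
  m <- match(material, ph$materials)
  if (is.na(m)) stop("unknown material '", material, "'")
  exp(approx(log(ph$energy), log(ph$muTot[, m]), xout = log(energy), rule = 2)$y)
}
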
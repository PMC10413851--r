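## Rigid-rotor harmonic-oscillator (RRHO) thermochemistry and Boltzmann
## tautomer populations. All energies are carried in the package's working
## unit, cm^-1 (per molecule).

#' Harmonic zero-point energy
#'
#' ZPE = (1/2) sum(omega) over the harmonic wavenumbers.
#'
#' @param freqs harmonic frequencies in cm^-1, all positive.
#' @return ZPE in cm^-1 (0 for an empty list).
#' @examples
#' zpe(c(100, 300))
#' @export
zpe <- function(freqs) {
  if (length(freqs) == 0) return(0)
  bad <- which(freqs <= 0)
  if (length(bad)) {
    stop("non-positive frequencies at mode(s) ", paste(bad, collapse = ", "),
         "; imaginary/negative modes cannot enter the harmonic ZPE")
  }
  sum(freqs) / 2
}

#' Species input for RRHO thermochemistry
#'
#' @param species_id identifier.
#' @param frequencies harmonic frequencies in cm^-1 (all > 0).
#' @param rotational a [rotational_set()] (equilibrium role) for the
#'   rotational partition function.
#' @param mass molecular mass in amu.
#' @param symmetry_number rotational symmetry number (default 1; all
#'   cytosine tautomers are C1/Cs).
#' @param electronic_degeneracy ground-state electronic degeneracy.
#' @return Object of class `"species_thermo"`.
#' @export
species_thermo <- function(species_id, frequencies, rotational, mass,
                           symmetry_number = 1, electronic_degeneracy = 1) {
  if (any(frequencies <= 0)) stop("thermo evaluation rejects non-positive frequencies")
  if (mass <= 0) stop("mass must be positive")
  if (symmetry_number < 1 || electronic_degeneracy < 1) {
    stop("symmetry number and electronic degeneracy must be positive integers")
  }
  structure(list(species_id = species_id, frequencies = frequencies,
                 rotational = rotational, mass = mass,
                 symmetry_number = symmetry_number,
                 electronic_degeneracy = electronic_degeneracy),
            class = "species_thermo")
}

#' RRHO thermodynamic functions
#'
#' Standard canonical-ensemble expressions for an ideal-gas rigid rotor /
#' harmonic oscillator at temperature `T`, reported per molecule in cm^-1:
#' translational, rotational (classical nonlinear-top) and vibrational
#' contributions to the internal energy and entropy, the zero-point energy,
#' and H(T) = U + kT, G(T) = H - T S. The translational entropy uses a
#' 1 atm standard state.
#'
#' @param s a [species_thermo()].
#' @param T temperature in K (> 0).
#' @param constants a [spectro_constants()] registry.
#' @return List with components (all cm^-1 unless noted): `ZPE`, `U_vib`,
#'   `S_vib` (cm^-1/K), `U_rot`, `S_rot`, `U_trans`, `S_trans`, `S_el`,
#'   `H`, `S` (cm^-1/K), `G`.
#' @export
rrho_thermo <- function(s, T, constants = spectro_constants()) {
  if (T <= 0) stop("temperature must be positive")
  kT <- constants$kB_cm1 * T
  w <- s$frequencies
  x <- w / kT
  U_vib <- sum(w / (exp(x) - 1))
  S_vib <- constants$kB_cm1 * sum(x / (exp(x) - 1) - log1p(-exp(-x)))

  ## rotational: classical partition function of a nonlinear top,
  ## q = sqrt(pi)/sigma * (kT)^(3/2) / sqrt(A B C), constants in cm^-1
  Bcm <- s$rotational$B * constants$mhz_to_cm1
  q_rot <- sqrt(pi) / s$symmetry_number * kT^1.5 / sqrt(prod(Bcm))
  U_rot <- 1.5 * kT
  S_rot <- constants$kB_cm1 * (log(q_rot) + 1.5)

  ## translational (Sackur-Tetrode, 1 atm standard state)
  m_kg <- s$mass * constants$amu
  kT_J <- constants$k * T
  p <- 101325
  lambda3 <- (constants$h / sqrt(2 * pi * m_kg * kT_J))^3
  q_trans <- kT_J / p / lambda3
  U_trans <- 1.5 * kT
  S_trans <- constants$kB_cm1 * (log(q_trans) + 2.5)

  S_el <- constants$kB_cm1 * log(s$electronic_degeneracy)
  ZPE <- zpe(w)
  H <- ZPE + U_vib + U_rot + U_trans + kT
  S <- S_vib + S_rot + S_trans + S_el
  list(temperature = T, ZPE = ZPE,
       U_vib = U_vib, S_vib = S_vib,
       U_rot = U_rot, S_rot = S_rot,
       U_trans = U_trans, S_trans = S_trans, S_el = S_el,
       H = H, S = S, G = H - T * S)
}

#' Boltzmann population ratios and mole fractions
#'
#' ratio_s = exp(-(E_s - E_ref) / (kB T)) relative to a reference species;
#' mole fractions are the normalized ratios. The energies may be relative
#' electronic energies or relative free energies — the basis is recorded,
#' not interpreted.
#'
#' @param rel_energies named numeric vector of relative energies in cm^-1.
#' @param T temperature in K.
#' @param reference reference species name (ratio 1).
#' @param basis `"electronic"` or `"free_energy"` (metadata only).
#' @param constants a [spectro_constants()] registry.
#' @return Object of class `"population_report"`: data.frame with columns
#'   `species`, `rel_energy`, `ratio`, `mole_fraction`, plus attributes
#'   `temperature`, `basis`, `reference`.
#' @examples
#' boltzmann_populations(c(EA = 0, EAc = 250.2, KA = 287.6, KI = 542.2), 450, "EA")
#' @export
boltzmann_populations <- function(rel_energies, T, reference,
                                  basis = c("electronic", "free_energy"),
                                  constants = spectro_constants()) {
  basis <- match.arg(basis)
  if (T <= 0) stop("temperature must be positive")
  if (is.null(names(rel_energies)) || !reference %in% names(rel_energies)) {
    stop("reference species '", reference, "' not present in rel_energies")
  }
  dE <- rel_energies - rel_energies[[reference]]
  ratio <- exp(-dE / (constants$kB_cm1 * T))
  out <- data.frame(species = names(rel_energies),
                    rel_energy = unname(dE),
                    ratio = unname(ratio),
                    mole_fraction = unname(ratio / sum(ratio)),
                    stringsAsFactors = FALSE)
  structure(out, class = c("population_report", "data.frame"),
            temperature = T, basis = basis, reference = reference)
}

#' Combined mole fraction of a group of species
#'
#' @param report a [boltzmann_populations()] report.
#' @param members character vector of species names (must all appear in the
#'   report; an empty set gives 0).
#' @return Summed mole fraction.
#' @examples
#' rep450 <- boltzmann_populations(c(EA = 0, EAc = 250.2, KA = 287.6, KI = 542.2),
#'                                 450, "EA")
#' group_mole_fraction(rep450, c("EA", "EAc"))
#' @export
group_mole_fraction <- function(report, members) {
  if (length(members) == 0) return(0)
  unknown <- setdiff(members, report$species)
  if (length(unknown)) {
    stop("unknown species in group: ", paste(unknown, collapse = ", "))
  }
  sum(report$mole_fraction[report$species %in% members])
}

#' Number of tautomers from site/proton combinatorics
#'
#' N_T = A! / (B! (A - B)!): the number of ways of distributing B labile
#' protons over A tautomeric sites. Exact integer arithmetic.
#'
#' @param A number of tautomeric sites (non-negative integer).
#' @param B number of labile protons, 0 <= B <= A.
#' @return The binomial coefficient as an integer-valued numeric.
#' @examples
#' tautomer_count(4, 2) # cytosine: 2 endo + 2 exo sites, 2 labile protons
#' @export
tautomer_count <- function(A, B) {
  if (A != round(A) || B != round(B)) stop("A and B must be integers")
  if (A < 0 || B < 0) stop("A and B must be non-negative")
  if (B > A) stop("B (", B, ") may not exceed A (", A, ")")
  round(choose(A, B))
}
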
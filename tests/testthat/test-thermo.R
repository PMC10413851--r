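test_that("harmonic ZPE is half the frequency sum and rejects bad modes", {
  expect_equal(zpe(numeric(0)), 0)
  expect_equal(zpe(c(100, 300)), 200)
  # full 33-mode high-level harmonic set: oracle is an independent column sum
  t6 <- load_fixture("table6_modes")
  expect_equal(zpe(t6$omega_rdsd_harm), sum(t6$omega_rdsd_harm) / 2)
  expect_error(zpe(c(100, -20, 300, 0)), "mode\\(s\\) 2, 4")
})

make_species <- function(id = "sp", freqs = c(300, 800, 1600), mass = 111.1,
                         B = c(3900, 2030, 1335)) {
  species_thermo(id, freqs,
                 rotational_set(id, "equilibrium", B[1], B[2], B[3], "test"),
                 mass = mass)
}

test_that("RRHO limits: vibrational heat vanishes at T->0 and reaches equipartition", {
  s <- make_species()
  lowT <- rrho_thermo(s, 1e-3)
  expect_equal(lowT$U_vib, 0, tolerance = 1e-10)
  expect_equal(lowT$ZPE, zpe(s$frequencies))
  # single mode at omega with kT = 100 omega: U_vib -> kT within 1%
  reg <- spectro_constants()
  w <- 50
  T_hot <- 100 * w / reg$kB_cm1
  s1 <- make_species(freqs = w)
  expect_equal(rrho_thermo(s1, T_hot)$U_vib, reg$kB_cm1 * T_hot,
               tolerance = 0.01)
  expect_error(rrho_thermo(s, -10), "positive")
})

test_that("G difference approaches dE + dZPE as T -> 0", {
  sA <- make_species("A", freqs = c(300, 800, 1600))
  sB <- make_species("B", freqs = c(350, 820, 1700))
  dZPE <- zpe(sB$frequencies) - zpe(sA$frequencies)
  dE <- 250
  dG <- function(T) {
    (dE + rrho_thermo(sB, T)$G) - rrho_thermo(sA, T)$G
  }
  # at very low T only ZPE survives of the vibrational part; the rotational
  # and translational parts are identical by construction except for
  # negligible terms since the species share mass and constants
  expect_equal(dG(0.01), dE + dZPE, tolerance = 1e-4)
})

test_that("translational free-energy difference follows the closed mass law", {
  reg <- spectro_constants()
  s1 <- make_species("m1", mass = 100)
  s2 <- make_species("m2", mass = 150)
  T <- 450
  dG <- rrho_thermo(s2, T)$G - rrho_thermo(s1, T)$G
  expect_equal(dG, -1.5 * reg$kB_cm1 * T * log(150 / 100), tolerance = 1e-8)
})

test_that("Boltzmann ratios at 450 K reproduce the published electronic-energy set", {
  rel <- c(EA = 0, EAc = 250.2, KA = 287.6, KI = 542.2)
  rep450 <- boltzmann_populations(rel, 450, "EA")
  expect_equal(round_half_away(rep450$ratio, 2), c(1.00, 0.45, 0.40, 0.18))
  expect_equal(sum(rep450$mole_fraction), 1, tolerance = 1e-10)
  expect_true(all(rep450$ratio > 0))
  expect_error(boltzmann_populations(rel, 450, "QQ"), "not present")
})

test_that("population ratios obey the temperature scaling and limit laws", {
  rel <- c(A = 0, B = 400, C = 900)
  # doubling energies at T equals original at T/2
  expect_equal(boltzmann_populations(2 * rel, 600, "A")$ratio,
               boltzmann_populations(rel, 300, "A")$ratio, tolerance = 1e-12)
  # T -> infinity: all ratios -> 1
  expect_equal(boltzmann_populations(rel, 1e9, "A")$ratio, rep(1, 3),
               tolerance = 1e-6)
  # monotone decreasing in energy at fixed T
  r <- boltzmann_populations(rel, 450, "A")$ratio
  expect_true(all(diff(r) < 0))
  # monotone increasing in T for species above the reference
  rT <- vapply(c(200, 400, 800), function(T) {
    boltzmann_populations(rel, T, "A")$ratio[2]
  }, numeric(1))
  expect_true(all(diff(rT) > 0))
})

test_that("mole fractions are reference-independent and group fractions add up", {
  rel <- c(EA = 0, EAc = 250.2, KA = 287.6, KI = 542.2)
  fr1 <- boltzmann_populations(rel, 450, "EA")
  fr2 <- boltzmann_populations(rel, 450, "KA")
  expect_equal(fr1$mole_fraction, fr2$mole_fraction, tolerance = 1e-12)
  expect_equal(group_mole_fraction(fr1, names(rel)), 1, tolerance = 1e-12)
  expect_equal(group_mole_fraction(fr1, character(0)), 0)
  expect_error(group_mole_fraction(fr1, c("EA", "nope")), "unknown species")
})

test_that("the published free-energy ratio set gives the combined enol-amino fraction 0.66", {
  ratios <- c(EA = 1.00, EAc = 0.45, KA = 0.60, KI = 0.16)
  fractions <- ratios / sum(ratios)
  rep_g <- structure(
    data.frame(species = names(ratios), rel_energy = NA_real_,
               ratio = unname(ratios), mole_fraction = unname(fractions)),
    class = c("population_report", "data.frame"))
  expect_equal(round_half_away(group_mole_fraction(rep_g, c("EA", "EAc")), 2),
               0.66)
})

test_that("zero-point energies pull the keto-amino form below the enol rotamer", {
  t4 <- load_fixture("table4_energies")
  rel <- setNames(t4$total, t4$species)
  dzpe <- setNames(t4$dZPE, t4$species)
  h0 <- rel + dzpe  # relative enthalpy at 0 K
  # raw electronic ordering: EAc below KA; ZPE inverts it
  expect_lt(rel[["EAc"]], rel[["KA"]])
  expect_lt(h0[["KA"]], h0[["EAc"]])
})

test_that("tautomer combinatorics match subset enumeration", {
  expect_identical(tautomer_count(4, 2), 6)  # 4 sites, 2 labile protons
  expect_identical(tautomer_count(7, 0), 1)
  expect_error(tautomer_count(3, 5), "may not exceed")
  expect_error(tautomer_count(-1, 0), "non-negative")
  set.seed(5)
  for (i in 1:10) {
    A <- sample(2:20, 1); B <- sample(0:A, 1)
    enumerated <- ncol(utils::combn(A, max(B, 1)))
    if (B == 0) enumerated <- 1
    expect_identical(tautomer_count(A, B), enumerated * 1)
    expect_identical(tautomer_count(A, B), tautomer_count(A, A - B))
  }
})
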
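test_that("rotational constants are Euclidean-invariant and mass-equivariant", {
  g <- random_geometry(5, seed = 21)
  B <- rotational_constants(g)$B
  for (s in 1:3) {
    Bm <- rotational_constants(rigid_motion(g, seed = s))$B
    expect_equal(Bm, B, tolerance = 1e-8)
  }
  # uniform mass scaling: B -> B / c
  g2 <- geometry(g$species_id, g$elements, g$coords, masses = 3 * g$masses)
  expect_equal(rotational_constants(g2)$B, B / 3, tolerance = 1e-10)
})

test_that("diatomic constants match the closed form B = K / (mu r^2)", {
  reg <- spectro_constants()
  m1 <- atomic_mass("C"); m2 <- atomic_mass("O"); r <- 1.128323
  g <- geometry("CO", c("C", "O"), rbind(c(0, 0, 0), c(0, 0, r)))
  B <- rotational_constants(g, linear = TRUE)$B
  mu <- m1 * m2 / (m1 + m2)
  closed <- reg$inertia_to_mhz / (mu * r^2)
  expect_true(is.na(B[["B_a"]]))
  expect_equal(unname(B[["B_b"]]), closed, tolerance = 1e-10)
  expect_equal(unname(B[["B_c"]]), closed, tolerance = 1e-10)
  # collinear without the linear flag is an error; single atom too
  expect_error(rotational_constants(g), "linear")
  expect_error(geometry("atom", "C", matrix(c(0, 0, 0), 1, 3)), "at least 2")
})

test_that("planar geometries satisfy I_c = I_a + I_b and zero inertial defect", {
  set.seed(31)
  xyz <- cbind(matrix(runif(10, -2, 2), 5, 2), 0)  # random planar 5-atom
  g <- geometry("planar", rep("C", 5), xyz)
  I <- inertia_moments(g)$moments
  expect_equal(I[3], I[1] + I[2], tolerance = 1e-8)
  expect_equal(inertial_defect(rotational_constants(g)), 0, tolerance = 1e-8)
})

test_that("out-of-plane mass gives a negative inertial defect, linear in mass", {
  # planar frame plus a light out-of-plane pair (pyramidalization proxy)
  base <- rbind(c(1.2, 0, 0), c(-1.2, 0, 0), c(0, 0.9, 0), c(0, -0.9, 0),
                c(0.3, 0.2, 0.4), c(0.3, 0.2, -0.4))
  g <- geometry("pyr", rep("C", 6), base)
  B <- rotational_constants(g)
  defect <- inertial_defect(B)
  # oracle: direct inertia computation
  I <- inertia_moments(g)$moments
  expect_equal(defect, I[3] - I[1] - I[2], tolerance = 1e-8)
  expect_lt(defect, 0)
  # scaling all masses by c scales the defect by c
  g3 <- geometry("pyr", g$elements, g$coords, masses = 3 * g$masses)
  expect_equal(inertial_defect(rotational_constants(g3)), 3 * defect,
               tolerance = 1e-8)
})

test_that("ground-state bookkeeping reproduces the published keto/enol rows", {
  dv_ka <- rotational_set("KA", "vibrational_correction", 29.1, 9.9, 8.1, "rDSD")
  b0_ka <- apply_vibrational_correction(
    rotational_set("KA", "equilibrium", 3904.3, 2035.9, 1338.5, "PCS"), dv_ka)
  expect_equal(unname(b0_ka$B), c(3875.2, 2026.0, 1330.4), tolerance = 1e-9)
  dv_ea <- rotational_set("EA", "vibrational_correction", 29.3, 11.6, 8.9, "rDSD")
  b0_ea <- apply_vibrational_correction(
    rotational_set("EA", "equilibrium", 3984.7, 2020.9, 1341.5, "PCS"), dv_ea)
  expect_equal(unname(b0_ea$B[1]), 3955.4, tolerance = 1e-9)
  # zero correction is the identity
  z <- rotational_set("KA", "vibrational_correction", 0, 0, 0, "none")
  eq <- rotational_set("KA", "equilibrium", 3904.3, 2035.9, 1338.5, "PCS")
  expect_equal(apply_vibrational_correction(eq, z)$B, eq$B)
  # species mismatch
  expect_error(apply_vibrational_correction(eq, dv_ea), "species mismatch")
})

test_that("semi-experimental constants recover the published imino rows to 0.1 MHz", {
  se_ki <- semi_experimental(
    rotational_set("KI", "ground_state", 3848.18174, 2026.31068, 1327.99167,
                   "experiment"),
    rotational_set("KI", "vibrational_correction", 29.4, 11.0, 7.7, "B3"))
  expect_equal(round_half_away(se_ki$B, 1), c(B_a = 3877.6, B_b = 2037.3,
                                              B_c = 1335.7))
  se_kic <- semi_experimental(
    rotational_set("KIc", "ground_state", 3861.2966, 2011.41032, 1323.19999,
                   "experiment"),
    rotational_set("KIc", "vibrational_correction", 28.4, 11.4, 7.7, "B3"))
  expect_equal(round_half_away(se_kic$B, 1), c(B_a = 3889.7, B_b = 2022.8,
                                               B_c = 1330.9))
  # zero correction leaves the experimental values unchanged
  z <- rotational_set("KI", "vibrational_correction", 0, 0, 0, "none")
  b0 <- rotational_set("KI", "ground_state", 3848.18174, 2026.31068,
                       1327.99167, "experiment")
  expect_equal(semi_experimental(b0, z)$B, b0$B)
})

test_that("correction and semi-experimental maps are mutual inverses", {
  eq <- rotational_set("sp", "equilibrium", 4000, 2000, 1300, "lvl")
  dv <- rotational_set("sp", "vibrational_correction", 27.5, 11.2, 8.3, "lvl")
  b0 <- apply_vibrational_correction(eq, dv)
  b0_as_exp <- rotational_set("sp", "ground_state", b0$B[1], b0$B[2], b0$B[3],
                              "experiment")
  expect_equal(semi_experimental(b0_as_exp, dv)$B, eq$B, tolerance = 1e-12)
})

test_that("error statistics reproduce the published uracil composite column", {
  comp <- rotational_set("uracil", "equilibrium", 3913.3, 2033.3, 1338.1, "PCS")
  se <- rotational_set("uracil", "equilibrium", 3913.3, 2035.2, 1338.9, "SE")
  st <- error_statistics(comp, se)
  expect_equal(round_half_away(st$MUE, 1), 0.9)
  expect_equal(round_half_away(st$MAX, 1), 1.9)
  expect_equal(round_half_away(st$MUE_pct, 2), 0.05)
  expect_equal(round_half_away(st$MAX_pct, 2), 0.09)
  # identical sets give all zeros
  st0 <- error_statistics(comp, comp)
  expect_equal(unlist(unclass(st0)), c(MUE = 0, MAX = 0, MUE_pct = 0,
                                       MAX_pct = 0))
})

test_that("per-axis triangle bound holds for mean unsigned errors", {
  set.seed(41)
  for (i in 1:20) {
    # well-separated constants so 1% perturbations cannot reorder them
    b <- c(4000, 2400, 1300) * runif(1, 0.8, 1.2)
    mk <- function(B) rotational_set("s", "equilibrium", B[1], B[2], B[3], "x")
    x <- mk(b); y <- mk(b * runif(3, 0.99, 1.01)); z <- mk(b * runif(3, 0.99, 1.01))
    sxy <- error_statistics(x, y); syz <- error_statistics(y, z)
    sxz <- error_statistics(x, z)
    expect_lte(sxz$MUE, sxy$MUE + syz$MUE + 1e-12)
  }
})
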
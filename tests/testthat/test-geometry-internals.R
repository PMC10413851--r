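test_that("XYZ round trip preserves geometries and malformed files fail with line numbers", {
  g <- geometry("water", c("O", "H", "H"),
                rbind(c(0, 0, 0.1173), c(0, 0.7572, -0.4692),
                      c(0, -0.7572, -0.4692)))
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(g, path)
  g2 <- read_xyz(path)
  expect_identical(g2$elements, g$elements)
  expect_equal(g2$coords, g$coords, tolerance = 1e-9)
  expect_equal(g2$masses, g$masses, tolerance = 1e-10)

  # whitespace-variant file parses identically
  lines <- readLines(path)
  lines[3:5] <- paste0("   ", gsub(" ", "   ", lines[3:5]))
  path2 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(lines, path2)
  g3 <- read_xyz(path2)
  expect_equal(g3$coords, g2$coords, tolerance = 1e-12)

  # count line disagreeing with body
  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("5", "too short", lines[3:5]), bad)
  expect_error(read_xyz(bad), "count line")
})

test_that("internal coordinates match independent vector-algebra oracles", {
  # two atoms 1 A apart on x
  g2 <- geometry("d", c("H", "H"), rbind(c(0, 0, 0), c(1, 0, 0)))
  spec_b <- internal_spec(data.frame(kind = "bond", i = 2, j = 1))
  expect_equal(as.numeric(extract_internals(g2, spec_b)), 1)

  # right-angle triatomic with unit legs
  g3 <- geometry("t", c("H", "H", "H"),
                 rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)))
  spec_a <- internal_spec(data.frame(kind = "angle", i = 1, j = 2, k = 3))
  expect_equal(as.numeric(extract_internals(g3, spec_a)), 90)

  # random 6-atom geometry vs law-of-cosines / axis-projection oracles
  g6 <- random_geometry(6, seed = 11)
  spec <- internal_spec(data.frame(
    kind = c("bond", "bond", "angle", "angle", "dihedral", "dihedral"),
    i = c(2, 5, 3, 6, 4, 6),
    j = c(1, 4, 2, 5, 3, 5),
    k = c(NA, NA, 1, 4, 2, 4),
    l = c(NA, NA, NA, NA, 1, 3)))
  vals <- extract_internals(g6, spec)
  xyz <- g6$coords
  expect_equal(as.numeric(vals), c(
    oracle_bond(xyz, 2, 1), oracle_bond(xyz, 5, 4),
    oracle_angle(xyz, 3, 2, 1), oracle_angle(xyz, 6, 5, 4),
    oracle_dihedral(xyz, 4, 3, 2, 1), oracle_dihedral(xyz, 6, 5, 4, 3)),
    tolerance = 1e-10)

  # collinear atoms make an angle undefined, error names the parameter
  gl <- geometry("lin", c("C", "C", "C"),
                 rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_error(extract_internals(gl, spec_a), "collinear.*angle\\(1-2-3\\)")
})

test_that("per-parameter combination applies the core-valence shift additively", {
  spec <- internal_spec(data.frame(kind = "bond", i = 2, j = 1))
  mk <- function(d) {
    extract_internals(geometry("s", c("C", "C"),
                               rbind(c(0, 0, 0), c(d, 0, 0))), spec)
  }
  # null shift leaves the base untouched
  expect_equal(as.numeric(geometry_scheme(mk(1.4), mk(1.39), mk(1.39))), 1.4)
  # bond 1.400 base, ae 1.395, fc 1.398 -> 1.397
  expect_equal(as.numeric(geometry_scheme(mk(1.400), mk(1.395), mk(1.398))),
               1.397, tolerance = 1e-12)
})

test_that("dihedral combination wraps on the circle", {
  spec <- internal_spec(data.frame(
    kind = c("bond", "bond", "bond", "angle", "angle", "dihedral"),
    i = c(2, 3, 4, 3, 4, 4), j = c(1, 2, 3, 2, 3, 3),
    k = c(NA, NA, NA, 1, 2, 2), l = c(NA, NA, NA, NA, NA, 1)))
  mk <- function(phi) {
    extract_internals(rebuild_cartesian(spec, c(1.5, 1.5, 1.5, 109, 109, phi)),
                      spec)
  }
  base <- mk(179); ae <- mk(100); fc <- mk(97)  # +3 degree shift
  comb <- geometry_scheme(base, ae, fc)
  expect_equal(unname(comb[6]), -178, tolerance = 1e-9)
})

test_that("rebuild round trip recovers internals to 1e-8 and rejects degenerate angles", {
  # water-like: 2 bonds + 1 angle
  spec3 <- internal_spec(data.frame(
    kind = c("bond", "bond", "angle"),
    i = c(2, 3, 3), j = c(1, 1, 1), k = c(NA, NA, 2)))
  r3 <- c(0.9572, 0.9572, 104.52)
  g3 <- rebuild_cartesian(spec3, r3)
  expect_equal(as.numeric(extract_internals(g3, spec3)), r3, tolerance = 1e-8)

  # 6-atom chain with dihedrals (ring-fragment-like backbone)
  spec6 <- internal_spec(data.frame(
    kind = c("bond",
             "bond", "angle",
             "bond", "angle", "dihedral",
             "bond", "angle", "dihedral",
             "bond", "angle", "dihedral"),
    i = c(2, 3, 3, 4, 4, 4, 5, 5, 5, 6, 6, 6),
    j = c(1, 2, 2, 3, 3, 3, 4, 4, 4, 5, 5, 5),
    k = c(NA, NA, 1, NA, 2, 2, NA, 3, 3, NA, 4, 4),
    l = c(NA, NA, NA, NA, NA, 1, NA, NA, 2, NA, NA, 3)))
  r6 <- c(1.52, 1.51, 112.0, 1.53, 110.5, 55.0, 1.50, 111.2, -58.0,
          1.54, 109.8, 175.0)
  g6 <- rebuild_cartesian(spec6, r6)
  expect_equal(as.numeric(extract_internals(g6, spec6)), r6, tolerance = 1e-8)

  # round trip through a random rigid motion of the rebuilt geometry
  g6r <- rigid_motion(g6, seed = 3)
  expect_equal(as.numeric(extract_internals(g6r, spec6)), r6, tolerance = 1e-8)

  # degenerate 180-degree placement request
  bad <- r6; bad[3] <- 180
  expect_error(rebuild_cartesian(spec6, bad), "degenerate")
})
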
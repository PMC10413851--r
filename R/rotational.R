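## Rigid-rotor rotational constants and the bookkeeping connecting
## equilibrium, ground-state and semi-experimental constants:
##   B0 = Beq - dBvib        (computed ground state)
##   Bse = B0_exp + dBvib    (semi-experimental equilibrium)

#' Rotational-constant set
#'
#' Constants (B_a, B_b, B_c) in MHz for one species, tagged with a role and
#' a provenance (level of theory or `"experiment"`). For every role except
#' `vibrational_correction` the set must satisfy B_a >= B_b >= B_c > 0.
#'
#' @param species_id species identifier.
#' @param role one of `"equilibrium"`, `"ground_state"`,
#'   `"semi_experimental"`, `"vibrational_correction"`.
#' @param B_a,B_b,B_c constants in MHz.
#' @param provenance free-text provenance tag.
#' @return Object of class `"rotational_set"`.
#' @export
rotational_set <- function(species_id,
                           role = c("equilibrium", "ground_state",
                                    "semi_experimental", "vibrational_correction"),
                           B_a, B_b, B_c, provenance = "unknown") {
  role <- match.arg(role)
  B <- c(B_a = as.numeric(B_a), B_b = as.numeric(B_b), B_c = as.numeric(B_c))
  if (role != "vibrational_correction") {
    finite <- B[is.finite(B)]
    if (any(finite <= 0)) stop("rotational constants must be positive (", species_id, ")")
    if (is.unsorted(rev(finite), strictly = FALSE)) {
      stop("rotational constants must satisfy B_a >= B_b >= B_c (", species_id, ")")
    }
  }
  structure(list(species_id = species_id, role = role, B = B,
                 provenance = provenance),
            class = "rotational_set")
}

#' @export
print.rotational_set <- function(x, ...) {
  cat("<rotational_set '", x$species_id, "' [", x$role, ", ", x$provenance,
      "]>\n", sep = "")
  print(round(x$B, 4))
  invisible(x)
}

#' Principal moments of inertia
#'
#' Center-of-mass shift, inertia tensor, and eigendecomposition with a
#' deterministic orientation convention (each principal axis flipped so its
#' largest-magnitude component is positive; ties broken by the first such
#' component).
#'
#' @param g a [geometry()].
#' @return List with `moments` (I_a <= I_b <= I_c, amu A^2) and `axes`
#'   (columns = principal axes).
#' @export
inertia_moments <- function(g) {
  m <- g$masses
  xyz <- sweep(g$coords, 2, colSums(g$coords * m) / sum(m))
  x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]
  I <- matrix(c(sum(m * (y^2 + z^2)), -sum(m * x * y), -sum(m * x * z),
                -sum(m * x * y), sum(m * (x^2 + z^2)), -sum(m * y * z),
                -sum(m * x * z), -sum(m * y * z), sum(m * (x^2 + y^2))),
              3, 3)
  e <- eigen(I, symmetric = TRUE)
  ord <- order(e$values)
  vals <- e$values[ord]; vecs <- e$vectors[, ord, drop = FALSE]
  for (j in 1:3) {
    v <- vecs[, j]
    top <- which.max(abs(v))
    if (v[top] < 0) vecs[, j] <- -v
  }
  list(moments = vals, axes = vecs)
}

#' Equilibrium rotational constants from a geometry
#'
#' Computes the principal moments of inertia and converts them to MHz with
#' the registry constant B = h / (8 pi^2 I): B_a >= B_b >= B_c correspond to
#' I_a <= I_b <= I_c. For linear arrangements the smallest moment vanishes;
#' pass `linear = TRUE` to obtain the two finite constants with B_a reported
#' as `NA` (absent), otherwise collinearity is an error.
#'
#' @param g a [geometry()] with at least 2 atoms.
#' @param linear declare the molecule linear.
#' @param provenance provenance tag for the resulting set.
#' @param constants a [spectro_constants()] registry.
#' @return A [rotational_set()] with role `"equilibrium"`.
#' @examples
#' co <- geometry("CO", c("C", "O"), rbind(c(0, 0, 0), c(0, 0, 1.128323)))
#' rotational_constants(co, linear = TRUE)
#' @export
rotational_constants <- function(g, linear = FALSE, provenance = "computed",
                                 constants = spectro_constants()) {
  if (n_atoms(g) < 2) stop("at least 2 atoms are required")
  im <- inertia_moments(g)
  I <- im$moments
  tol <- max(I) * 1e-10
  if (I[1] <= tol && !linear) {
    stop("geometry is collinear; pass linear = TRUE for a linear rotor")
  }
  B <- ifelse(I > tol, constants$inertia_to_mhz / I, NA_real_)
  rotational_set(g$species_id, "equilibrium",
                 B_a = B[1], B_b = B[2], B_c = B[3], provenance = provenance)
}

.check_species <- function(a, b) {
  if (!identical(a$species_id, b$species_id)) {
    stop("species mismatch: '", a$species_id, "' vs '", b$species_id, "'")
  }
}

#' Ground-state constants from equilibrium constants and vibrational corrections
#'
#' B0_i = Beq_i - dBvib_i per inertial axis. The sign convention (the
#' correction is subtracted) is fixed package-wide; see the methods
#' vignette for its derivation from cross-checking published tables.
#'
#' @param B_eq [rotational_set()] with role `"equilibrium"`.
#' @param dB_vib [rotational_set()] with role `"vibrational_correction"`.
#' @return A [rotational_set()] with role `"ground_state"`.
#' @examples
#' eq <- rotational_set("KA", "equilibrium", 3904.3, 2035.9, 1338.5, "PCS")
#' dv <- rotational_set("KA", "vibrational_correction", 29.1, 9.9, 8.1, "rDSD/j3")
#' apply_vibrational_correction(eq, dv)
#' @export
apply_vibrational_correction <- function(B_eq, dB_vib) {
  .check_species(B_eq, dB_vib)
  if (B_eq$role != "equilibrium") stop("B_eq must have role 'equilibrium'")
  if (dB_vib$role != "vibrational_correction") {
    stop("dB_vib must have role 'vibrational_correction'")
  }
  B <- B_eq$B - dB_vib$B
  rotational_set(B_eq$species_id, "ground_state", B[1], B[2], B[3],
                 provenance = paste0(B_eq$provenance, " - ", dB_vib$provenance))
}

#' Semi-experimental equilibrium constants
#'
#' Bse_i = B0_i(experiment) + dBvib_i(computed): the experimental
#' ground-state constants are freed of zero-point vibrational motion using
#' a computed correction, yielding the reference standard against which
#' computed equilibrium constants are judged.
#'
#' @param B0_exp [rotational_set()] with role `"ground_state"` (experiment).
#' @param dB_vib [rotational_set()] with role `"vibrational_correction"`.
#' @return A [rotational_set()] with role `"semi_experimental"`.
#' @export
semi_experimental <- function(B0_exp, dB_vib) {
  .check_species(B0_exp, dB_vib)
  if (B0_exp$role != "ground_state") stop("B0_exp must have role 'ground_state'")
  if (dB_vib$role != "vibrational_correction") {
    stop("dB_vib must have role 'vibrational_correction'")
  }
  B <- B0_exp$B + dB_vib$B
  rotational_set(B0_exp$species_id, "semi_experimental", B[1], B[2], B[3],
                 provenance = paste0(B0_exp$provenance, " + ", dB_vib$provenance))
}

#' Error statistics over the three rotational constants
#'
#' Mean and maximum unsigned errors of a computed set against a reference
#' set, absolute (MHz) and relative (% of the reference constant):
#' MUE = mean |dB_i|, MAX = max |dB_i|, MUE% = mean 100 |dB_i| / B_i_ref,
#' MAX% = max 100 |dB_i| / B_i_ref.
#'
#' @param computed,reference [rotational_set()]s for the same species with
#'   three finite constants each.
#' @return List of class `"rotor_error_stats"` with `MUE`, `MAX` (MHz),
#'   `MUE_pct`, `MAX_pct` (%).
#' @export
error_statistics <- function(computed, reference) {
  .check_species(computed, reference)
  if (any(!is.finite(computed$B)) || any(!is.finite(reference$B))) {
    stop("error statistics need three finite constants on both sides")
  }
  if (any(reference$B <= 0)) stop("reference constants must be positive")
  d <- abs(computed$B - reference$B)
  rel <- 100 * d / reference$B
  structure(list(MUE = mean(d), MAX = max(d),
                 MUE_pct = mean(rel), MAX_pct = max(rel)),
            class = "rotor_error_stats")
}

#' @export
print.rotor_error_stats <- function(x, ...) {
  cat(sprintf("MUE %.1f MHz  MAX %.1f MHz  MUE%% %.2f  MAX%% %.2f\n",
              x$MUE, x$MAX, x$MUE_pct, x$MAX_pct))
  invisible(x)
}

#' Inertial defect
#'
#' Delta = I_c - I_a - I_b (amu A^2), with the moments reconstructed from
#' the rotational constants through the registry conversion. Zero for a
#' rigid planar molecule; negative values diagnose out-of-plane mass (e.g.
#' slight amino-group pyramidalization).
#'
#' @param B a [rotational_set()] with three finite constants.
#' @param constants a [spectro_constants()] registry.
#' @return The inertial defect in amu A^2.
#' @export
inertial_defect <- function(B, constants = spectro_constants()) {
  if (any(!is.finite(B$B))) stop("inertial defect needs three finite constants")
  I <- constants$inertia_to_mhz / B$B
  unname(I["B_c"] - I["B_a"] - I["B_b"])
}
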
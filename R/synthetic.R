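## Seeded synthetic generators used to validate the analysis pipeline:
## rigid rotors with prescribed principal moments, energy series obeying an
## exact inverse-power basis-set convergence law, and random mode tables.
## Same seed + parameters -> identical output.

#' Synthetic rigid rotor with prescribed principal moments
#'
#' Builds a point-mass geometry whose principal moments of inertia equal
#' the requested (I_a <= I_b <= I_c) exactly, by closed form: pairs of
#' equal masses at unit distance on each principal axis, with
#' m_x = (I_b + I_c - I_a)/4, m_y = (I_a + I_c - I_b)/4,
#' m_z = (I_a + I_b - I_c)/4. A planar rotor (I_c = I_a + I_b) gets
#' m_z = 0 and the z pair is dropped. Triples violating I_c <= I_a + I_b
#' are unphysical and rejected. The geometry is then rigidly rotated and
#' translated at random (seeded), which leaves the moments unchanged.
#'
#' @param moments numeric length-3, target principal moments in amu A^2,
#'   sorted ascending, all positive.
#' @param seed integer seed for the random rigid motion; `NULL` leaves the
#'   rotor on its principal axes.
#' @param species_id identifier for the geometry.
#' @return A [geometry()] of abstract mass points (element `"X"`).
#' @examples
#' g <- synthetic_rigid_rotor(c(50, 80, 120), seed = 1)
#' inertia_moments(g)$moments
#' @export
synthetic_rigid_rotor <- function(moments, seed = NULL, species_id = "rotor") {
  if (length(moments) != 3 || any(moments <= 0)) {
    stop("moments must be three positive values")
  }
  if (is.unsorted(moments)) stop("moments must be sorted ascending (I_a <= I_b <= I_c)")
  Ia <- moments[1]; Ib <- moments[2]; Ic <- moments[3]
  if (Ic > Ia + Ib + 1e-12 * Ic) {
    stop("infeasible moment triple: I_c <= I_a + I_b must hold for mass points")
  }
  m_axis <- c((Ib + Ic - Ia) / 4, (Ia + Ic - Ib) / 4, (Ia + Ib - Ic) / 4)
  coords <- NULL; masses <- NULL
  for (ax in 1:3) {
    if (m_axis[ax] <= 1e-12 * max(m_axis)) next  # planar/degenerate: drop pair
    e <- c(0, 0, 0); e[ax] <- 1
    coords <- rbind(coords, e, -e)
    masses <- c(masses, m_axis[ax], m_axis[ax])
  }
  if (nrow(coords) < 2) stop("degenerate moment triple leaves fewer than 2 mass points")
  if (!is.null(seed)) {
    old <- .Random.seed_exists()
    on.exit(.restore_seed(old), add = TRUE)
    set.seed(seed)
    Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    shift <- stats::rnorm(3, sd = 5)
    coords <- coords %*% t(Q) + rep(1, nrow(coords)) %o% shift
  }
  geometry(species_id, rep("X", nrow(coords)), coords, masses = masses)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Synthetic basis-set convergence series
#'
#' E(k) = E_cbs + A k^-p evaluated at the requested basis cardinals: an
#' exact inverse-power convergence law for exercising the two-point
#' extrapolation (which recovers `E_cbs` exactly when `p` matches its
#' exponent).
#'
#' @param E_cbs basis-set-limit energy.
#' @param A amplitude of the convergence term.
#' @param cardinals integer vector of basis cardinal numbers.
#' @param p convergence exponent (> 0), default 3.
#' @return data.frame with columns `cardinal` and `energy`.
#' @examples
#' s <- synthetic_cbs_series(-99.1234, 0.5, 3:4)
#' cbs_two_point(s$energy[1], s$energy[2], 3, 4)$value
#' @export
synthetic_cbs_series <- function(E_cbs, A, cardinals = 3:4, p = 3) {
  if (p <= 0) stop("convergence exponent must be positive")
  if (any(cardinals <= 0)) stop("cardinals must be positive")
  data.frame(cardinal = cardinals, energy = E_cbs + A * cardinals^(-p))
}

#' Synthetic vibrational mode table
#'
#' Seeded random mode set in the layout consumed by [build_spectrum()]:
#' high- and low-level harmonic frequencies drawn over a spectroscopic
#' range, anharmonic fundamentals displaced by moderate negative-leaning
#' shifts, and optionally a prescribed number of large-amplitude failure
#' modes (non-positive anharmonic fundamentals) to exercise the fallback.
#'
#' @param n_modes number of modes.
#' @param seed integer seed.
#' @param n_failures how many modes get a non-positive anharmonic value.
#' @param freq_range range of the low-level harmonic frequencies, cm^-1.
#' @param shift_sd standard deviation of the anharmonic shift, cm^-1.
#' @return data.frame with columns `mode`, `label`, `omega_low`,
#'   `nu_low_anh`, `omega_high`, `intensity`.
#' @export
synthetic_mode_set <- function(n_modes = 33, seed = 1, n_failures = 0,
                               freq_range = c(100, 3800), shift_sd = 40) {
  if (n_failures > n_modes) stop("n_failures may not exceed n_modes")
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  omega_low <- sort(stats::runif(n_modes, freq_range[1], freq_range[2]),
                    decreasing = TRUE)
  omega_high <- omega_low * stats::runif(n_modes, 0.98, 1.02)
  shift <- -abs(stats::rnorm(n_modes, mean = shift_sd, sd = shift_sd / 2))
  nu_anh <- omega_low + shift
  if (n_failures > 0) {
    fail_at <- sample(n_modes, n_failures)
    nu_anh[fail_at] <- -abs(nu_anh[fail_at])
  }
  data.frame(mode = seq_len(n_modes),
             label = sprintf("mode%02d", seq_len(n_modes)),
             omega_low = round(omega_low),
             nu_low_anh = round(nu_anh),
             omega_high = round(omega_high),
             intensity = round(stats::rexp(n_modes, 1 / 50), 1))
}
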
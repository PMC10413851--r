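## Hybrid anharmonic IR assembly: harmonic frequencies from a high level of
## theory corrected by anharmonic shifts from a cheaper level,
##   nu_hybrid = omega_high + (nu_anh_low - omega_low),
## with a harmonic fallback for large-amplitude modes (amino-group
## inversion) where second-order vibrational perturbation theory breaks
## down and can even return negative fundamentals.

#' Hybrid frequency for one mode
#'
#' Normally returns `omega_high + (nu_low_anh - omega_low)`. The fallback
#' policy returns the bare high-level harmonic (flag set) when the
#' low-level anharmonic fundamental is non-positive or when the magnitude
#' of the anharmonic shift exceeds `shift_threshold` — both symptoms of a
#' large-amplitude mode outside the perturbative regime.
#'
#' @param omega_high high-level harmonic frequency, cm^-1 (> 0). Vectorized.
#' @param omega_low low-level harmonic frequency, cm^-1 (> 0).
#' @param nu_low_anh low-level anharmonic fundamental, cm^-1 (may be
#'   negative, signalling VPT2 failure).
#' @param shift_threshold fallback trigger on |nu_low_anh - omega_low|,
#'   default 300 cm^-1.
#' @return List with numeric `hybrid` and logical `fallback`, both aligned
#'   with the inputs.
#' @examples
#' hybrid_frequency(3793, 3715, 3525)          # 3603
#' hybrid_frequency(348, 321, -216)$fallback   # TRUE
#' @export
hybrid_frequency <- function(omega_high, omega_low, nu_low_anh,
                             shift_threshold = 300) {
  if (any(omega_high <= 0) || any(omega_low <= 0)) {
    stop("harmonic frequencies must be positive")
  }
  shift <- nu_low_anh - omega_low
  fallback <- nu_low_anh <= 0 | abs(shift) > shift_threshold
  hybrid <- ifelse(fallback, omega_high, omega_high + shift)
  list(hybrid = hybrid, fallback = fallback)
}

#' Assemble a hybrid vibrational spectrum table
#'
#' Applies [hybrid_frequency()] mode by mode and returns the assembled
#' table sorted by mode index. Intensities are carried unchanged from the
#' high-level harmonic calculation.
#'
#' @param modes data.frame with columns `mode` (unique indices, contiguous
#'   from 1), `label`, `omega_low`, `nu_low_anh`, `omega_high` and
#'   optionally `intensity`.
#' @param species_id species identifier.
#' @param shift_threshold passed to [hybrid_frequency()].
#' @return Object of class `"spectrum_table"` (a data.frame) with added
#'   columns `anh_shift`, `hybrid`, `fallback`, and attributes `species_id`
#'   and `shift_threshold`.
#' @export
build_spectrum <- function(modes, species_id, shift_threshold = 300) {
  modes <- as.data.frame(modes)
  need <- c("mode", "label", "omega_low", "nu_low_anh", "omega_high")
  miss <- setdiff(need, names(modes))
  if (length(miss)) stop("missing mode columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(modes$mode)) stop("duplicate mode indices")
  modes <- modes[order(modes$mode), , drop = FALSE]
  if (!identical(as.integer(modes$mode), seq_len(nrow(modes)))) {
    stop("mode indices must be contiguous from 1")
  }
  if (!"intensity" %in% names(modes)) modes$intensity <- NA_real_
  hf <- hybrid_frequency(modes$omega_high, modes$omega_low, modes$nu_low_anh,
                         shift_threshold)
  modes$anh_shift <- as.numeric(modes$nu_low_anh - modes$omega_low)
  modes$hybrid <- as.numeric(hf$hybrid)
  modes$fallback <- hf$fallback
  rownames(modes) <- NULL
  structure(modes, class = c("spectrum_table", "data.frame"),
            species_id = species_id, shift_threshold = shift_threshold)
}

#' Assign computed modes to observed bands
#'
#' One-to-one greedy nearest-frequency matching: computed modes are taken
#' in order of decreasing intensity and matched to the nearest unclaimed
#' observed band within `window`. This mirrors manual spectroscopic
#' practice and is deterministic; unmatched entries are reported on both
#' sides.
#'
#' @param spectrum a [build_spectrum()] table.
#' @param observed data.frame with columns `frequency` and optionally
#'   `intensity` (cm^-1; an empty frame leaves every mode unassigned).
#' @param window maximum |residual| for a match, cm^-1 (> 0).
#' @return List with `assignments` (data.frame: mode, hybrid, observed,
#'   residual; `observed` NA where unassigned) and `unassigned_observed`
#'   (indices into `observed` never claimed).
#' @export
assign_bands <- function(spectrum, observed, window = 30) {
  if (window <= 0) stop("window must be positive")
  observed <- as.data.frame(observed)
  n_obs <- nrow(observed)
  taken <- logical(n_obs)
  pri <- order(-ifelse(is.na(spectrum$intensity), -Inf, spectrum$intensity),
               spectrum$mode)
  obs_of_mode <- rep(NA_integer_, nrow(spectrum))
  for (r in pri) {
    if (n_obs == 0) break
    d <- abs(observed$frequency - spectrum$hybrid[r])
    d[taken] <- Inf
    jbest <- which.min(d)
    if (is.finite(d[jbest]) && d[jbest] <= window) {
      obs_of_mode[r] <- jbest
      taken[jbest] <- TRUE
    }
  }
  assignments <- data.frame(
    mode = spectrum$mode,
    hybrid = spectrum$hybrid,
    observed = ifelse(is.na(obs_of_mode), NA_real_,
                      observed$frequency[obs_of_mode]),
    residual = NA_real_
  )
  assignments$residual <- assignments$observed - assignments$hybrid
  list(assignments = assignments,
       unassigned_observed = which(!taken))
}
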
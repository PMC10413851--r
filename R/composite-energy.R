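## Composite electronic-energy layer: explicitly correlated coupled-cluster
## base term, two-point complete-basis-set (CBS) extrapolation carried out at
## the MP2-F12 level, and a core-valence (CV) correction from all-electron
## minus frozen-core differences. The total is a plain additive composite:
##   E = E[CCSD(T)-F12/3F12] + dCBS + dCV

.same_unit <- function(...) {
  qs <- list(...)
  units <- vapply(qs, function(q) q$unit, character(1))
  if (length(unique(units)) != 1) {
    stop("energy unit mismatch: ", paste(units, collapse = " vs "))
  }
  units[[1]]
}

.as_energy <- function(x, unit = "cm-1") {
  if (inherits(x, "energy")) x else energy(x, unit)
}

#' Two-point complete-basis-set extrapolation
#'
#' Extrapolates the infinite-basis limit of a correlation-consistent energy
#' series assumed to follow E(k) = E_CBS + A k^-p (default p = 3, the
#' standard inverse-cube law) through the two points (n, E_n) and (m, E_m):
#' E_CBS = (m^p E_m - n^p E_n) / (m^p - n^p). The formula is exact on any
#' series of that form.
#'
#' @param E_n,E_m energies ([energy()] or numeric in `unit`) at basis
#'   cardinal numbers `n` and `m`.
#' @param n,m distinct positive basis cardinal numbers (e.g. 3 and 4).
#' @param p convergence exponent, default 3.
#' @param unit unit assumed for bare numeric input.
#' @return The extrapolated [energy()].
#' @examples
#' # exact recovery from a synthetic inverse-cube series
#' cbs_two_point(-99.1234 + 0.5 / 27, -99.1234 + 0.5 / 64, 3, 4)
#' @export
cbs_two_point <- function(E_n, E_m, n, m, p = 3, unit = "cm-1") {
  if (n == m) stop("basis cardinals must differ (n == m == ", n, ")")
  if (n <= 0 || m <= 0) stop("basis cardinals must be positive")
  E_n <- .as_energy(E_n, unit); E_m <- .as_energy(E_m, unit)
  u <- .same_unit(E_n, E_m)
  energy((m^p * E_m$value - n^p * E_n$value) / (m^p - n^p), u)
}

#' CBS correction term of the composite energy
#'
#' The difference between the MP2-F12 basis-set limit, extrapolated from
#' triple- and quadruple-zeta F12 energies by [cbs_two_point()], and the
#' MP2-F12 energy in the same basis as the coupled-cluster base term:
#' dCBS = CBS(E_T, E_Q) - E_base.
#'
#' @param E_mp2_T,E_mp2_Q MP2-F12 energies at cardinals 3 and 4.
#' @param E_mp2_base MP2-F12 energy in the base (triple-zeta F12) basis.
#' @param extrapolate `"total"` (default) or `"correlation-only"`; recorded
#'   on the result as attribute `extrapolation_mode` (which pair of numbers
#'   the caller designated is not inspected further).
#' @param unit unit assumed for bare numeric input.
#' @return The dCBS [energy()], with attribute `extrapolation_mode`.
#' @export
cbs_correction <- function(E_mp2_T, E_mp2_Q, E_mp2_base,
                           extrapolate = c("total", "correlation-only"),
                           unit = "cm-1") {
  extrapolate <- match.arg(extrapolate)
  E_mp2_T <- .as_energy(E_mp2_T, unit)
  E_mp2_Q <- .as_energy(E_mp2_Q, unit)
  E_mp2_base <- .as_energy(E_mp2_base, unit)
  u <- .same_unit(E_mp2_T, E_mp2_Q, E_mp2_base)
  lim <- cbs_two_point(E_mp2_T, E_mp2_Q, 3, 4)
  out <- energy(lim$value - E_mp2_base$value, u)
  attr(out, "extrapolation_mode") <- extrapolate
  out
}

#' Core-valence correction
#'
#' Correlation contribution of the core electrons, evaluated as the
#' difference between all-electron and frozen-core results at a common
#' level and basis: dCV = E_ae - E_fc. When [level_energy()] records are
#' supplied, their level tags must agree.
#'
#' @param E_ae,E_fc all-electron and frozen-core energies ([energy()],
#'   numeric, or [level_energy()] records).
#' @param unit unit assumed for bare numeric input.
#' @return The dCV [energy()].
#' @export
cv_correction <- function(E_ae, E_fc, unit = "cm-1") {
  if (inherits(E_ae, "level_energy") && inherits(E_fc, "level_energy")) {
    if (!identical(E_ae$level, E_fc$level)) {
      stop("level mismatch between ae ('", E_ae$level, "') and fc ('",
           E_fc$level, "') records")
    }
    if (!identical(E_ae$core_treatment, "all-electron") ||
        !identical(E_fc$core_treatment, "frozen-core")) {
      stop("cv_correction expects (all-electron, frozen-core) records, got (",
           E_ae$core_treatment, ", ", E_fc$core_treatment, ")")
    }
    E_ae <- E_ae$energy; E_fc <- E_fc$energy
  }
  E_ae <- .as_energy(E_ae, unit); E_fc <- .as_energy(E_fc, unit)
  u <- .same_unit(E_ae, E_fc)
  energy(E_ae$value - E_fc$value, u)
}

#' One species x level electronic-energy record
#'
#' @param species_id species identifier.
#' @param level level-of-theory tag, e.g. `"CC-F12/3F12"`, `"MP2-F12/4F12"`.
#' @param core_treatment `"frozen-core"` or `"all-electron"`.
#' @param energy an [energy()] (or numeric in `unit`).
#' @param unit unit assumed for bare numeric input.
#' @return Object of class `"level_energy"`.
#' @export
level_energy <- function(species_id, level,
                         core_treatment = c("frozen-core", "all-electron"),
                         energy, unit = "cm-1") {
  core_treatment <- match.arg(core_treatment)
  structure(list(species_id = species_id, level = level,
                 core_treatment = core_treatment,
                 energy = .as_energy(energy, unit)),
            class = "level_energy")
}

#' Assemble the composite total energy
#'
#' Adds the three composite terms for one species and stores the breakdown:
#' total = base + dCBS + dCV. All three must share one unit.
#'
#' @param species_id species identifier.
#' @param base coupled-cluster base energy.
#' @param delta_cbs CBS correction, e.g. from [cbs_correction()].
#' @param delta_cv core-valence correction, e.g. from [cv_correction()].
#' @param unit unit assumed for bare numeric input.
#' @return Object of class `"composite_breakdown"` with fields `species_id`,
#'   `base`, `delta_cbs`, `delta_cv`, `total` and the extrapolation-mode
#'   flag carried over from `delta_cbs` (default `"total"`).
#' @examples
#' composite_total("KA", 320.0, -8.5, -23.9)$total
#' @export
composite_total <- function(species_id, base, delta_cbs, delta_cv, unit = "cm-1") {
  mode <- attr(delta_cbs, "extrapolation_mode")
  base <- .as_energy(base, unit)
  delta_cbs <- .as_energy(delta_cbs, unit)
  delta_cv <- .as_energy(delta_cv, unit)
  u <- .same_unit(base, delta_cbs, delta_cv)
  structure(list(species_id = species_id,
                 base = base, delta_cbs = delta_cbs, delta_cv = delta_cv,
                 total = energy(base$value + delta_cbs$value + delta_cv$value, u),
                 extrapolation_mode = if (is.null(mode)) "total" else mode),
            class = "composite_breakdown")
}

#' @export
print.composite_breakdown <- function(x, ...) {
  cat("<composite_breakdown '", x$species_id, "'> (", x$total$unit, ")\n", sep = "")
  cat(sprintf("  base  %12.4f\n  dCBS  %12.4f\n  dCV   %12.4f\n  total %12.4f\n",
              x$base$value, x$delta_cbs$value, x$delta_cv$value, x$total$value))
  invisible(x)
}

#' Relative electronic energies against a reference species
#'
#' @param breakdowns list of [composite_total()] breakdowns (or a named numeric
#'   vector of totals in cm^-1).
#' @param reference species_id of the reference (maps to 0).
#' @param constants a [spectro_constants()] registry, used to express the
#'   result in cm^-1 whatever the breakdown unit.
#' @return Named numeric vector of relative energies in cm^-1.
#' @export
relative_energies <- function(breakdowns, reference,
                              constants = spectro_constants()) {
  if (is.numeric(breakdowns)) {
    totals <- breakdowns
    if (is.null(names(totals))) stop("numeric totals must be named by species")
  } else {
    totals <- vapply(breakdowns, function(b) {
      convert_energy(b$total, "cm-1", constants = constants)$value
    }, numeric(1))
    names(totals) <- vapply(breakdowns, function(b) b$species_id, character(1))
  }
  if (anyDuplicated(names(totals))) stop("duplicate species in breakdowns")
  if (!reference %in% names(totals)) {
    stop("reference species '", reference, "' not present")
  }
  totals - totals[[reference]]
}
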
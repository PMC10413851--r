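## Internal-coordinate layer for the per-parameter geometry combination
## ("geometry scheme"): a base-level optimized structure is corrected, one
## geometrical parameter at a time, by the core-valence shift obtained from
## all-electron minus frozen-core optimizations at a common level.

#' Internal-coordinate specification
#'
#' An ordered list of bond / angle / dihedral definitions over atom indices
#' of a [geometry()]. For Cartesian reconstruction with
#' [rebuild_cartesian()] the spec must be in Z-matrix order: one bond for
#' atom 2, bond + angle for atom 3, and bond + angle + dihedral for each
#' later atom, each referring only to already-placed atoms.
#'
#' @param params data.frame with columns `kind` (`"bond"`, `"angle"`,
#'   `"dihedral"`), `i`, `j`, `k`, `l` (1-based atom indices; `k`, `l` NA
#'   where unused). Bonds are in Angstrom, angles/dihedrals in degrees.
#' @return Object of class `"internal_spec"`.
#' @export
internal_spec <- function(params) {
  params <- as.data.frame(params)
  needed <- c("kind", "i", "j")
  if (!all(needed %in% names(params))) {
    stop("params needs columns kind, i, j (and k, l where applicable)")
  }
  if (!"k" %in% names(params)) params$k <- NA_integer_
  if (!"l" %in% names(params)) params$l <- NA_integer_
  for (r in seq_len(nrow(params))) {
    kind <- params$kind[r]
    idx <- switch(kind,
                  bond = c(params$i[r], params$j[r]),
                  angle = c(params$i[r], params$j[r], params$k[r]),
                  dihedral = c(params$i[r], params$j[r], params$k[r], params$l[r]),
                  stop("unknown parameter kind '", kind, "' at row ", r))
    if (any(is.na(idx))) stop("missing atom index in ", kind, " at row ", r)
    if (anyDuplicated(idx)) stop("repeated atom index in ", kind, " at row ", r)
  }
  structure(params[c("kind", "i", "j", "k", "l")], class = c("internal_spec", "data.frame"))
}

param_labels <- function(spec) {
  apply(spec, 1, function(r) {
    idx <- r[c("i", "j", "k", "l")]
    idx <- idx[!is.na(idx)]
    paste0(r[["kind"]], "(", paste(trimws(idx), collapse = "-"), ")")
  })
}

.vnorm <- function(v) sqrt(sum(v * v))

bond_length <- function(xyz, i, j) .vnorm(xyz[i, ] - xyz[j, ])

bond_angle <- function(xyz, i, j, k, label = NULL) {
  u <- xyz[i, ] - xyz[j, ]; v <- xyz[k, ] - xyz[j, ]
  nu <- .vnorm(u); nv <- .vnorm(v)
  if (nu == 0 || nv == 0) stop("coincident atoms in ", label)
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

dihedral_angle <- function(xyz, i, j, k, l, label = NULL) {
  b1 <- xyz[j, ] - xyz[i, ]; b2 <- xyz[k, ] - xyz[j, ]; b3 <- xyz[l, ] - xyz[k, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (.vnorm(n1) < 1e-10 || .vnorm(n2) < 1e-10) {
    stop("collinear atoms make dihedral ", label, " undefined")
  }
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  x <- sum(n1 * n2); y <- sum(m1 * n2) / .vnorm(b2)
  ## negated so the canonical case (l rotated by +phi about j->k from i's
  ## half-plane) reads +phi, matching the convention of the major
  ## molecular-mechanics libraries; kept in (-180, 180]
  wrap_degrees(-atan2(y, x) * 180 / pi)
}

#' Wrap an angle in degrees to (-180, 180]
#' @param x numeric vector of angles in degrees.
#' @return Wrapped angles.
#' @export
wrap_degrees <- function(x) {
  w <- (x + 180) %% 360 - 180
  ifelse(w == -180, 180, w)
}

#' Measure internal coordinates on a Cartesian geometry
#'
#' @param g a [geometry()].
#' @param spec an [internal_spec()].
#' @return Numeric vector aligned with `spec` (Angstrom / degrees), with
#'   parameter labels as names and the spec attached as attribute `"spec"`.
#'   Angles whose defining atoms are collinear are an error naming the
#'   parameter.
#' @export
extract_internals <- function(g, spec) {
  stopifnot(inherits(spec, "internal_spec"))
  n <- n_atoms(g)
  idx <- unlist(spec[c("i", "j", "k", "l")])
  if (any(idx[!is.na(idx)] > n)) stop("spec refers to atoms beyond the geometry")
  labs <- param_labels(spec)
  xyz <- g$coords
  vals <- numeric(nrow(spec))
  for (r in seq_len(nrow(spec))) {
    vals[r] <- switch(spec$kind[r],
      bond = bond_length(xyz, spec$i[r], spec$j[r]),
      angle = {
        a <- bond_angle(xyz, spec$i[r], spec$j[r], spec$k[r], labs[r])
        if (a <= 1e-8 || a >= 180 - 1e-8) {
          stop("collinear atoms in ", labs[r])
        }
        a
      },
      dihedral = dihedral_angle(xyz, spec$i[r], spec$j[r], spec$k[r], spec$l[r], labs[r]))
  }
  names(vals) <- labs
  attr(vals, "spec") <- spec
  vals
}

.check_aligned <- function(a, b) {
  sa <- attr(a, "spec"); sb <- attr(b, "spec")
  if (length(a) != length(b)) stop("parameter vectors have different lengths")
  if (!is.null(sa) && !is.null(sb) && !identical(as.data.frame(sa), as.data.frame(sb))) {
    stop("parameter vectors are aligned to different internal-coordinate specs")
  }
}

#' Per-parameter additive geometry combination
#'
#' Applies the geometry scheme r_comb\[i\] = r_base\[i\] + (r_ae\[i\] -
#' r_fc\[i\]): the base-level structure is shifted, parameter by parameter,
#' by the core-valence change seen between all-electron and frozen-core
#' optimizations. Dihedral arithmetic is carried out on the circle
#' (shortest signed difference; result wrapped to (-180, 180]).
#'
#' @param r_base,r_ae,r_fc parameter vectors from [extract_internals()],
#'   aligned to one [internal_spec()].
#' @param spec the spec; taken from `r_base`'s attribute when omitted.
#' @return Combined parameter vector, aligned with `spec`.
#' @export
geometry_scheme <- function(r_base, r_ae, r_fc, spec = attr(r_base, "spec")) {
  .check_aligned(r_base, r_ae); .check_aligned(r_base, r_fc)
  if (is.null(spec)) stop("an internal_spec is required (none attached to r_base)")
  out <- numeric(length(r_base))
  for (r in seq_along(out)) {
    if (spec$kind[r] == "dihedral") {
      shift <- wrap_degrees(r_ae[r] - r_fc[r])
      out[r] <- wrap_degrees(r_base[r] + shift)
    } else {
      out[r] <- r_base[r] + (r_ae[r] - r_fc[r])
    }
  }
  if (any(spec$kind == "bond" & out <= 0)) stop("combination produced a non-positive bond length")
  names(out) <- names(r_base)
  attr(out, "spec") <- spec
  out
}

#' Rebuild Cartesian coordinates from internal coordinates
#'
#' Inverse of [extract_internals()] for Z-matrix-ordered specs: atom 1 at
#' the origin, atom 2 along +z, atom 3 in the xz-plane, later atoms placed
#' by the standard bond/angle/dihedral construction from three
#' already-placed reference atoms.
#'
#' @param spec an [internal_spec()] in Z-matrix order.
#' @param r parameter vector aligned with `spec`.
#' @param species_id identifier for the rebuilt geometry.
#' @param elements,masses atom annotations for the result; `elements`
#'   defaults to `"X"` with unit masses.
#' @return A [geometry()] such that `extract_internals()` recovers `r`
#'   (angles within 1e-8). Near-linear reference angles are an error.
#' @export
rebuild_cartesian <- function(spec, r, species_id = "rebuilt",
                              elements = NULL, masses = NULL) {
  stopifnot(inherits(spec, "internal_spec"))
  if (length(r) != nrow(spec)) stop("parameter vector does not match spec")
  ## group parameters by the atom they place (the first index)
  n <- max(unlist(spec[c("i", "j", "k", "l")]), na.rm = TRUE)
  placed <- rep(FALSE, n); placed[1] <- TRUE
  xyz <- matrix(0, n, 3)
  rows_for <- function(atom) which(spec$i == atom)
  get_param <- function(atom, kind) {
    rr <- rows_for(atom)
    rr <- rr[spec$kind[rr] == kind]
    if (length(rr) != 1) {
      stop("spec is not in Z-matrix order: atom ", atom, " needs exactly one ",
           kind, " placing it, found ", length(rr))
    }
    rr
  }
  deg2rad <- pi / 180
  for (atom in 2:n) {
    rb <- get_param(atom, "bond")
    jb <- spec$j[rb]
    if (!placed[jb]) stop("spec is not in Z-matrix order: bond reference ", jb,
                          " of atom ", atom, " not yet placed")
    d <- r[rb]
    if (d <= 0) stop("non-positive bond length for atom ", atom)
    if (atom == 2) {
      xyz[atom, ] <- xyz[jb, ] + c(0, 0, d)
      placed[atom] <- TRUE
      next
    }
    ra <- get_param(atom, "angle")
    if (spec$j[ra] != jb) stop("angle of atom ", atom, " must pivot on its bond reference")
    ka <- spec$k[ra]
    if (!placed[ka]) stop("spec is not in Z-matrix order: angle reference ", ka,
                          " of atom ", atom, " not yet placed")
    theta <- r[ra]
    if (theta <= 1e-8 || theta >= 180 - 1e-8) {
      stop("degenerate placement angle (", theta, " deg) for atom ", atom)
    }
    if (atom == 3) {
      ## place in the xz-plane relative to jb -> ka axis
      phi <- 0
      la <- NA_integer_
    } else {
      rd <- get_param(atom, "dihedral")
      if (spec$j[rd] != jb || spec$k[rd] != ka) {
        stop("dihedral of atom ", atom, " must extend its bond/angle references")
      }
      la <- spec$l[rd]
      if (!placed[la]) stop("spec is not in Z-matrix order: dihedral reference ", la,
                            " of atom ", atom, " not yet placed")
      phi <- r[rd]
    }
    ## NeRF-style placement: references B = jb (bonded), C = ka, D = la
    B <- xyz[jb, ]; C <- xyz[ka, ]
    bc <- B - C
    nbc <- .vnorm(bc)
    if (nbc < 1e-10) stop("coincident reference atoms for atom ", atom)
    u <- bc / nbc
    if (atom == 3 || is.na(la)) {
      ## any vector not parallel to u defines the plane
      helper <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    } else {
      helper <- xyz[la, ] - C
    }
    n1 <- c(u[2] * helper[3] - u[3] * helper[2],
            u[3] * helper[1] - u[1] * helper[3],
            u[1] * helper[2] - u[2] * helper[1])
    if (.vnorm(n1) < 1e-10) {
      stop("unresolvable placement for atom ", atom, ": reference frame is (near-)linear")
    }
    n1 <- n1 / .vnorm(n1)
    m1 <- c(n1[2] * u[3] - n1[3] * u[2],
            n1[3] * u[1] - n1[1] * u[3],
            n1[1] * u[2] - n1[2] * u[1])
    ## the bond A-B must make the supplied angle with C-B: component along
    ## u = (B-C)/|BC| is -cos(theta)
    th <- theta * deg2rad; ph <- phi * deg2rad
    disp <- d * (-cos(th) * u + sin(th) * (cos(ph) * m1 + sin(ph) * n1))
    xyz[atom, ] <- B + disp
    placed[atom] <- TRUE
  }
  if (is.null(elements)) {
    elements <- rep("X", n)
    if (is.null(masses)) masses <- rep(1, n)
  }
  geometry(species_id, elements, xyz, masses = masses)
}
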
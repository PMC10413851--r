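# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: distances via dist(), angles via the law of
# cosines, rotational constants via the closed diatomic form, binomials via
# subset enumeration.

oracle_bond <- function(xyz, i, j) {
  as.numeric(dist(rbind(xyz[i, ], xyz[j, ])))
}

# angle at j from the three pairwise distances (law of cosines)
oracle_angle <- function(xyz, i, j, k) {
  a <- oracle_bond(xyz, i, j); b <- oracle_bond(xyz, j, k)
  c2 <- oracle_bond(xyz, i, k)^2
  acos((a^2 + b^2 - c2) / (2 * a * b)) * 180 / pi
}

# dihedral i-j-k-l via projections onto the plane normal to j->k
oracle_dihedral <- function(xyz, i, j, k, l) {
  axis <- xyz[k, ] - xyz[j, ]
  axis <- axis / sqrt(sum(axis^2))
  proj <- function(v) v - sum(v * axis) * axis
  u <- proj(xyz[i, ] - xyz[j, ])
  w <- proj(xyz[l, ] - xyz[k, ])
  cross <- c(u[2] * w[3] - u[3] * w[2],
             u[3] * w[1] - u[1] * w[3],
             u[1] * w[2] - u[2] * w[1])
  ang <- atan2(sum(cross * axis), sum(u * w)) * 180 / pi
  ang
}

random_geometry <- function(n, seed, species = "rand") {
  set.seed(seed)
  repeat {
    xyz <- matrix(rnorm(3 * n, sd = 1.5), n, 3)
    # reject nearly coincident atoms so angles stay well-defined
    if (min(dist(xyz)) > 0.5) break
  }
  geometry(species, rep("C", n), xyz)
}

rigid_motion <- function(g, seed) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  t <- rnorm(3, sd = 10)
  geometry(g$species_id, g$elements,
           g$coords %*% t(Q) + rep(1, nrow(g$coords)) %o% t,
           masses = g$masses)
}

# published isotopic masses (AME-derived), used as the lookup oracle
ORACLE_MASS_H1 <- 1.00782503207
ORACLE_MASS_C13 <- 13.00335483507
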
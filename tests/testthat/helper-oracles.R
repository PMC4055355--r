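# Independent oracles, deliberately coded from different formulas than the
# package internals, plus small fixture builders.

# textbook torsion formula: atan2(|b2| b1.(b2 x b3), (b1 x b2).(b2 x b3))
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  y <- sqrt(sum(b2^2)) * sum(b1 * cross(b2, b3))
  x <- sum(cross(b1, b2) * cross(b2, b3))
  a <- atan2(y, x) * 180 / pi
  if (a <= -180) a + 360 else a
}

# Horn quaternion method: optimal-superposition RMSD from the largest
# eigenvalue of the 4x4 key matrix
oracle_rmsd_quaternion <- function(ref, mov) {
  x <- sweep(ref, 2, colMeans(ref))
  y <- sweep(mov, 2, colMeans(mov))
  S <- t(y) %*% x
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(x^2) + sum(y^2) - 2 * lam) / nrow(ref)
  sqrt(max(0, msd))
}

# all-pairs double loop clash counter
oracle_clash_count <- function(lxyz, lr, env, scale) {
  n <- 0L
  for (i in seq_len(nrow(lxyz))) for (j in seq_len(nrow(env))) {
    d <- sqrt(sum((lxyz[i, ] - c(env$x[j], env$y[j], env$z[j]))^2))
    if (d < scale * (lr[i] + env$vdw[j])) n <- n + 1L
  }
  n
}

# exposed area of sphere 1 (radius r1) partially covered by sphere 2
# (radius r2) at centre distance d: full sphere minus the spherical cap
oracle_two_sphere_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * r1^2)
  x1 <- (d^2 + r1^2 - r2^2) / (2 * d)
  h1 <- r1 - x1
  4 * pi * r1^2 - 2 * pi * r1 * h1
}

# random rigid transform (rotation via QR of a Gaussian matrix)
random_rigid <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = rnorm(3, sd = 10))
}

# ideal backbone stub for building labels outside a full model
ideal_backbone <- function() {
  rbind(N = c(0, 0, 0), CA = c(1.458, 0, 0), C = c(2.009, 1.422, 0))
}

# minimal hand-written two-atom PDB text
minimal_pdb_text <- function() {
  c("CRYST1   10.000   10.000   10.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "END")
}
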
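# Shared fixture builders. Everything is generated in code; no binary or
# stored data.

# independent torsion oracle: the textbook atan2 cross/dot formulation,
# written against named intermediate vectors rather than the package's
# vectorised kernel, so the two routes share no code.
oracle_torsion <- function(p1, p2, p3, p4) {
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cr(b1, b2)
  n2 <- cr(b2, b3)
  m1 <- cr(n1, b2 / sqrt(sum(b2^2)))
  # sign convention: positive torsion = clockwise far-bond rotation
  # looking from atom 2 toward atom 3 (matches bio3d::torsion.xyz)
  deg <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  deg <- -deg
  if (deg <= -180) deg + 360 else deg
}

# random proper rigid transform (rotation via QR of a Gaussian matrix,
# determinant fixed to +1, plus a random translation)
random_rigid_transform <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(rotation = q, translation = rnorm(3, sd = 5))
}

apply_rigid <- function(xyz, tr) {
  sweep(xyz %*% tr$rotation, 2, tr$translation, "+")
}

# quartet with prescribed internal coordinates, via the package's
# z-matrix placement (first three atoms fixed, fourth set by torsion)
quartet_with_torsion <- function(phi, bond = 1.53, angle = 111) {
  a <- c(0, 0, 0)
  b <- c(bond, 0, 0)
  cc <- ligmode:::zmat_place(c(0, 1, 0), a, b, bond, angle, 0)
  d <- ligmode:::zmat_place(a, b, cc, bond, angle, phi)
  rbind(a, b, cc, d)
}

# minimal trajectory: given a vector of torsions, one 4-atom system with
# that chain torsion per frame (plus nothing else)
toy_torsion_frames <- function(phis, replica_id = 1L) {
  atoms <- tibble::tibble(
    atom_name = c("C1", "C2", "C3", "C4"),
    residue_name = "LIG", residue_id = 900L, chain_id = "L", element = "C"
  )
  coords <- array(0, dim = c(length(phis), 4, 3))
  for (i in seq_along(phis)) coords[i, , ] <- quartet_with_torsion(phis[i])
  ligmode::traj_frames(atoms, coords, replica_id = replica_id)
}

# bare state tibble for coupling tests
state_df <- function(states, scheme = NULL, replica_id = 1L) {
  df <- tibble::tibble(replica_id = replica_id,
                       frame = seq_along(states),
                       state = if (is.factor(states)) states
                               else factor(states, levels = unique(states)))
  if (!is.null(scheme)) {
    structure(df, scheme = scheme,
              class = c("state_tbl", class(tibble::tibble())))
  } else df
}
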
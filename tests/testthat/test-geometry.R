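test_that("torsion reproduces the canonical planar cases", {
  expect_equal(torsion(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  expect_equal(torsion(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)), 180)
  # perpendicular half-planes: +90 under the right-hand convention,
  # cross-checked symbolically via the oracle
  p <- list(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, 1))
  expect_equal(torsion(p[[1]], p[[2]], p[[3]], p[[4]]), 90)
  expect_equal(do.call(oracle_torsion, p), 90)
  # mirror reflection flips the sign
  pm <- lapply(p, function(v) c(v[1], v[2], -v[3]))
  expect_equal(torsion(pm[[1]], pm[[2]], pm[[3]], pm[[4]]), -90)
})

test_that("torsion agrees with the independent oracle on random quartets", {
  set.seed(42)
  for (i in 1:1000) {
    p <- matrix(rnorm(12, sd = 2), 4, 3)
    expect_equal(torsion(p[1, ], p[2, ], p[3, ], p[4, ]),
                 oracle_torsion(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
  }
})

test_that("torsion is invariant under proper rigid transforms and flips under reflection", {
  set.seed(7)
  p <- matrix(rnorm(12, sd = 2), 4, 3)
  ref <- torsion(p[1, ], p[2, ], p[3, ], p[4, ])
  for (i in 1:100) {
    tr <- random_rigid_transform()
    q <- apply_rigid(p, tr)
    expect_equal(torsion(q[1, ], q[2, ], q[3, ], q[4, ]), ref,
                 tolerance = 1e-9)
  }
  refl <- p %*% diag(c(1, 1, -1))
  expect_equal(torsion(refl[1, ], refl[2, ], refl[3, ], refl[4, ]), -ref,
               tolerance = 1e-9)
})

test_that("torsion output stays in (-180, 180] and respects 360-degree wraps", {
  for (phi in c(-179.5, -90, -0.5, 0, 0.5, 90, 179.5, 180)) {
    q <- quartet_with_torsion(phi)
    got <- torsion(q[1, ], q[2, ], q[3, ], q[4, ])
    expect_gt(got, -180)
    expect_lte(got, 180)
    expect_equal(got, wrap_angle(phi), tolerance = 1e-9)
    # building with phi + 360 is the same geometry
    q2 <- quartet_with_torsion(phi + 360)
    expect_equal(torsion(q2[1, ], q2[2, ], q2[3, ], q2[4, ]), got,
                 tolerance = 1e-9)
  }
})

test_that("degenerate torsion geometry raises structured errors", {
  expect_error(torsion(c(0, 1, 0), c(0, 0, 0), c(0, 0, 0), c(1, 1, 0)),
               class = "ligmode_degenerate_geometry")
  expect_error(torsion(c(2, 0, 0), c(1, 0, 0), c(0, 0, 0), c(1, 1, 0)),
               class = "ligmode_degenerate_geometry")
})

test_that("torsion_series evaluates prescribed angles per frame and names bad frames", {
  phis <- c(-90, 90, 180, -60)
  fr <- toy_torsion_frames(phis, replica_id = 3L)
  ts <- torsion_series(fr, 1:4, label = "chain")
  expect_s3_class(ts, "torsion_tbl")
  expect_equal(ts$value, phis, tolerance = 1e-6)
  expect_equal(ts$replica_id, rep(3L, 4))
  expect_equal(ts$frame, 1:4)

  one <- torsion_series(toy_torsion_frames(45), 1:4)
  expect_equal(nrow(one), 1)

  # frame 2 degenerate: second and third atoms coincide
  fr$coords[2, 3, ] <- fr$coords[2, 2, ]
  expect_error(torsion_series(fr, 1:4), "frame 2",
               class = "ligmode_degenerate_geometry")
})

test_that("ring centroid is the unweighted mean and follows translations", {
  hex <- t(vapply(0:5, function(k) {
    1.39 * c(cos(k * pi / 3), sin(k * pi / 3), 0)
  }, numeric(3)))
  atoms <- tibble::tibble(atom_name = paste0("C", 1:6),
                          residue_name = "PHE", residue_id = 336L,
                          chain_id = "A", element = "C")
  coords <- array(0, dim = c(2, 6, 3))
  coords[1, , ] <- hex
  coords[2, , ] <- sweep(hex, 2, c(1, 2, 3), "+")
  fr <- traj_frames(atoms, coords)
  cen <- ring_centroid(fr, 1:6)
  expect_equal(cen[1, ], c(0, 0, 0), tolerance = 1e-9)
  expect_equal(cen[2, ], c(1, 2, 3), tolerance = 1e-9)
  # 3-atom "ring" is just the mean of three points
  cen3 <- ring_centroid(fr, 1:3)
  expect_equal(cen3[1, ], colMeans(hex[1:3, ]), tolerance = 1e-12)
  expect_error(ring_centroid(fr, 1:2), class = "ligmode_config_error")
})

test_that("min distance equals the exhaustive pairwise minimum", {
  atoms <- tibble::tibble(atom_name = paste0("X", 1:7),
                          residue_name = "UNK", residue_id = 1L,
                          chain_id = "A", element = "C")
  # fixed-point example: group {(0,0,0),(0,0,4)} vs point (0,0,5) -> 1
  coords <- array(0, dim = c(1, 7, 3))
  coords[1, 2, ] <- c(0, 0, 4)
  coords[1, 3:7, ] <- matrix(rnorm(15), 5, 3)
  fr <- traj_frames(atoms, coords)
  d <- min_distance_series(fr, 1:2, c(0, 0, 5))
  expect_equal(d$value, 1.0)
  expect_equal(min_distance_series(fr, 1, matrix(c(0, 0, 0), 1))$value, 0)

  # random groups vs brute force over all pairs, multiple frames
  set.seed(99)
  coords <- array(rnorm(6 * 7 * 3, sd = 3), dim = c(6, 7, 3))
  fr <- traj_frames(atoms, coords)
  d <- min_distance_series(fr, 1:5, 6:7)
  brute <- vapply(1:6, function(i) {
    min(vapply(1:5, function(a) {
      min(vapply(6:7, function(b) {
        sqrt(sum((coords[i, a, ] - coords[i, b, ])^2))
      }, numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(d$value, brute, tolerance = 1e-12)
  expect_error(min_distance_series(fr, integer(0), 6:7),
               class = "ligmode_config_error")
})

test_that("kabsch recovers known transforms exactly and excludes reflections", {
  set.seed(5)
  x <- matrix(rnorm(30), 10, 3)
  id <- kabsch_superpose(x, x)
  expect_equal(id$rotation, diag(3), tolerance = 1e-9)
  expect_equal(id$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(id$rmsd, 0, tolerance = 1e-12)

  th <- pi / 6
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  y <- sweep(x %*% rot, 2, c(1, 0, 0), "+")
  k <- kabsch_superpose(x, y)
  expect_equal(k$rotation, rot, tolerance = 1e-9)
  expect_equal(k$translation, c(1, 0, 0), tolerance = 1e-9)
  expect_lt(k$rmsd, 1e-9)
  expect_equal(det(k$rotation), 1, tolerance = 1e-9)

  # a reflected cloud must still map through a proper rotation
  yr <- x %*% diag(c(1, 1, -1))
  kr <- kabsch_superpose(x, yr)
  expect_equal(det(kr$rotation), 1, tolerance = 1e-9)

  expect_error(kabsch_superpose(x[1:2, ], x[1:2, ]),
               class = "ligmode_config_error")
})

test_that("kabsch rmsd is symmetric and never beaten by random rigid transforms", {
  set.seed(21)
  x <- matrix(rnorm(150), 50, 3)
  y <- x + matrix(rnorm(150, sd = 0.1), 50, 3)
  tr <- random_rigid_transform()
  y <- apply_rigid(y, tr)
  k <- kabsch_superpose(x, y)
  expect_equal(k$rmsd, kabsch_superpose(y, x)$rmsd, tolerance = 1e-9)
  for (i in 1:1000) {
    rt <- random_rigid_transform()
    cand <- sqrt(mean(rowSums((apply_rigid(x, rt) - y)^2)))
    expect_gte(cand, k$rmsd - 1e-12)
  }
})

test_that("ligand RMSD is zero under rigid motion and tracks pure ligand shifts", {
  set.seed(3)
  atoms <- tibble::tibble(
    atom_name = c(rep("CA", 6), paste0("C", 1:4)),
    residue_name = c(rep("GLY", 6), rep("LIG", 4)),
    residue_id = c(1:6, rep(900L, 4)),
    chain_id = c(rep("A", 6), rep("L", 4)),
    element = "C"
  )
  base <- matrix(rnorm(30, sd = 4), 10, 3)
  # frames 2-4: whole system rigidly moved
  coords <- array(0, dim = c(4, 10, 3))
  coords[1, , ] <- base
  for (i in 2:4) coords[i, , ] <- apply_rigid(base, random_rigid_transform())
  fr <- traj_frames(atoms, coords)
  rs <- ligand_rmsd_series(fr, 1:6, 7:10)
  expect_equal(rs$value, rep(0, 4), tolerance = 1e-9)

  # receptor fixed, ligand translated by 2 A in frame 2
  coords2 <- array(0, dim = c(2, 10, 3))
  coords2[1, , ] <- base
  coords2[2, , ] <- base
  coords2[2, 7:10, ] <- sweep(base[7:10, ], 2, c(0, 0, 2), "+")
  fr2 <- traj_frames(atoms, coords2)
  rs2 <- ligand_rmsd_series(fr2, 1:6, 7:10)
  expect_equal(rs2$value, c(0, 2), tolerance = 1e-9)
  expect_error(ligand_rmsd_series(fr2, 1:6, 7:10, reference_frame = 9),
               class = "ligmode_invalid_input")
})

test_that("series export to CSV keeps the shared column contract", {
  fr <- toy_torsion_frames(c(10, 20), replica_id = 2L)
  ts <- torsion_series(fr, 1:4, label = "chain")
  path <- withr::local_tempfile(fileext = ".csv")
  write_series_csv(ts, path)
  back <- utils::read.csv(path)
  expect_equal(names(back), c("replica_id", "frame", "label", "value"))
  expect_equal(back$value, ts$value)
})
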
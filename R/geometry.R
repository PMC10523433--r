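# Per-frame series are plain tibbles (replica_id, frame, label, value)
# with a subclass tag so autoplot() can dispatch. dplyr verbs may drop
# the tag; every consumer only requires the columns.
new_series_tbl <- function(values, label, replica_id, subclass,
                           frame = seq_along(values)) {
  structure(
    tibble(replica_id = as.integer(replica_id), frame = as.integer(frame),
           label = label, value = as.numeric(values)),
    class = c(subclass, "ligmode_series", class(tibble()))
  )
}

#' Signed torsion (dihedral) angle of four points
#'
#' IUPAC-signed torsion from the cross/dot atan2 formulation: looking
#' down the 2->3 bond, a clockwise rotation of the far bond is positive.
#' Anti-periplanar is reported as +180 degrees (the range is the
#' half-open interval (-180, 180]).
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom), or N x 3 matrices to
#'   evaluate N quartets at once.
#' @return Torsion angle(s) in degrees, in (-180, 180].
#' @examples
#' torsion(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))  # 0 (syn)
#' torsion(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)) # 180 (anti)
#' @export
torsion <- function(p1, p2, p3, p4) {
  as_mat <- function(p) if (is.matrix(p)) p else matrix(p, nrow = 1)
  p1 <- as_mat(p1); p2 <- as_mat(p2); p3 <- as_mat(p3); p4 <- as_mat(p4)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  cross_m <- function(u, v) {
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  }
  n1 <- cross_m(b1, b2)
  n2 <- cross_m(b2, b3)
  b2n <- sqrt(rowSums(b2^2))
  if (any(b2n < 1e-10)) {
    abort("degenerate geometry: central-bond atoms coincide",
          class = "ligmode_degenerate_geometry")
  }
  if (any(rowSums(n1^2) < 1e-20) || any(rowSums(n2^2) < 1e-20)) {
    abort("degenerate geometry: collinear atom triple in torsion",
          class = "ligmode_degenerate_geometry")
  }
  x <- rowSums(n1 * n2)
  y <- rowSums(cross_m(n1, n2) * (b2 / b2n))
  ang <- wrap_angle(rad2deg(atan2(y, x)))
  if (nrow(p1) == 1) ang[1] else ang
}

#' Per-frame torsion series over a trajectory
#'
#' Evaluates the signed torsion of one atom quartet in every frame, e.g.
#' the ligand chain dihedral 1-2-3-4 or a side-chain chi1.
#'
#' @param frames A [traj_frames] object.
#' @param quartet Integer vector of 4 atom indices, in dihedral order.
#' @param label Series label carried into exported tables.
#' @return A tibble (`torsion_tbl`) with columns `replica_id`, `frame`,
#'   `label`, `value` (degrees in (-180, 180]).
#' @export
torsion_series <- function(frames, quartet, label = "torsion") {
  stopifnot(inherits(frames, "traj_frames"))
  if (length(quartet) != 4 || any(quartet < 1) || any(quartet > n_atoms(frames))) {
    abort("quartet must be 4 valid atom indices", class = "ligmode_invalid_input")
  }
  get <- function(j) matrix(frames$coords[, quartet[j], ], ncol = 3)
  vals <- tryCatch(
    torsion(get(1), get(2), get(3), get(4)),
    ligmode_degenerate_geometry = function(e) {
      # re-run frame by frame to name the offender
      for (i in seq_len(n_frames(frames))) {
        ok <- tryCatch({
          torsion(frames$coords[i, quartet[1], ],
                  frames$coords[i, quartet[2], ],
                  frames$coords[i, quartet[3], ],
                  frames$coords[i, quartet[4], ])
          TRUE
        }, ligmode_degenerate_geometry = function(e2) FALSE)
        if (!ok) {
          abort(sprintf("degenerate torsion geometry at frame %d", i),
                class = "ligmode_degenerate_geometry")
        }
      }
      abort(conditionMessage(e), class = "ligmode_degenerate_geometry")
    })
  if (n_frames(frames) == 1) vals <- vals[1]
  new_series_tbl(vals, label, frames$replica_id, "torsion_tbl")
}

#' Per-frame centroid of a ring (or any atom group)
#'
#' Unweighted arithmetic mean of the member coordinates in each frame —
#' the standard construction for an aromatic-ring centroid.
#'
#' @param frames A [traj_frames] object.
#' @param ring_indices At least 3 atom indices.
#' @return Numeric `frames x 3` matrix of centroid coordinates (Angstrom).
#' @export
ring_centroid <- function(frames, ring_indices) {
  stopifnot(inherits(frames, "traj_frames"))
  if (length(ring_indices) < 3) {
    abort("ring centroid needs at least 3 atoms", class = "ligmode_config_error")
  }
  sub <- frames$coords[, ring_indices, , drop = FALSE]
  apply(sub, c(1, 3), mean)
}

#' Minimum group-to-target distance per frame
#'
#' For each frame, the minimum Euclidean distance over all pairs between
#' the atoms of `group_a` and the target. The target may be another atom
#' group or a per-frame point (e.g. a ring centroid): multi-candidate
#' selections such as a dimethyl pair or leucine's two delta-carbons are
#' thereby reduced by one rule — the closest contact.
#'
#' @param frames A [traj_frames] object.
#' @param group_a Integer atom indices (nonempty).
#' @param target Integer atom indices, or a `frames x 3` matrix of
#'   per-frame points, or a single 3-vector used for all frames.
#' @param label Series label.
#' @return A tibble (`distance_tbl`) with columns `replica_id`, `frame`,
#'   `label`, `value` (Angstrom).
#' @export
min_distance_series <- function(frames, group_a, target, label = "distance") {
  stopifnot(inherits(frames, "traj_frames"))
  if (length(group_a) < 1) {
    abort("group_a must be nonempty", class = "ligmode_config_error")
  }
  nf <- n_frames(frames)
  a <- frames$coords[, group_a, , drop = FALSE]
  if (is.numeric(target) && !is.matrix(target) && length(target) == 3) {
    target <- matrix(target, nrow = nf, ncol = 3, byrow = TRUE)
  }
  if (is.matrix(target)) {
    if (nrow(target) != nf || ncol(target) != 3) {
      abort("per-frame target must be a frames x 3 matrix",
            class = "ligmode_config_error")
    }
    b <- array(target, dim = c(nf, 1, 3))
  } else {
    if (length(target) < 1) {
      abort("target must be nonempty", class = "ligmode_config_error")
    }
    b <- frames$coords[, target, , drop = FALSE]
  }
  vals <- vapply(seq_len(nf), function(i) {
    am <- matrix(a[i, , ], ncol = 3)
    bm <- matrix(b[i, , ], ncol = 3)
    d2 <- outer(rowSums(am^2), rowSums(bm^2), "+") - 2 * am %*% t(bm)
    sqrt(max(0, min(d2)))
  }, numeric(1))
  new_series_tbl(vals, label, frames$replica_id, "distance_tbl")
}

#' Kabsch least-squares rigid superposition
#'
#' Closed-form SVD solution for the proper rotation (reflections
#' excluded) and translation minimising the RMSD between two paired
#' point sets. Row-vector convention: the fitted coordinates are
#' `mobile %*% rotation + translation` (row-wise).
#'
#' @param mobile,reference Paired `N x 3` coordinate matrices, N >= 3.
#' @return List with `rotation` (3 x 3, det +1), `translation`
#'   (3-vector) and `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3 ||
      nrow(mobile) < 3) {
    abort("kabsch needs paired N x 3 matrices with N >= 3",
          class = "ligmode_config_error")
  }
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  x0 <- sweep(mobile, 2, cm)
  y0 <- sweep(reference, 2, cr)
  s <- svd(t(x0) %*% y0)
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- x0 %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - y0)^2)))
  list(rotation = rot, translation = as.numeric(cr - cm %*% rot), rmsd = rmsd)
}

# apply a kabsch transform to an N x 3 matrix
apply_transform <- function(xyz, transform) {
  sweep(xyz %*% transform$rotation, 2, transform$translation, "+")
}

#' Ligand RMSD after receptor-only superposition
#'
#' Each frame is rigidly superposed onto the reference frame using the
#' receptor fit atoms only (Kabsch), then the RMSD over the ligand atoms
#' is computed with no further fitting — so the series reports genuine
#' ligand pose changes within the binding pocket, not global tumbling.
#' The reference defaults to the first frame (the initial docked pose).
#'
#' @param frames A [traj_frames] object.
#' @param fit_indices Receptor atom indices used for superposition
#'   (typically alpha-carbons), N >= 3.
#' @param ligand_indices Ligand (heavy-)atom indices scored by RMSD.
#' @param reference_frame Frame index of the reference pose (default 1).
#' @param label Series label.
#' @return A tibble (`rmsd_tbl`) with columns `replica_id`, `frame`,
#'   `label`, `value` (Angstrom); the reference frame scores 0.
#' @export
ligand_rmsd_series <- function(frames, fit_indices, ligand_indices,
                               reference_frame = 1L, label = "ligand_rmsd") {
  stopifnot(inherits(frames, "traj_frames"))
  nf <- n_frames(frames)
  if (reference_frame < 1 || reference_frame > nf) {
    abort(sprintf("reference_frame %d out of range [1, %d]",
                  reference_frame, nf),
          class = "ligmode_invalid_input")
  }
  if (length(ligand_indices) < 1) {
    abort("ligand selection is empty", class = "ligmode_config_error")
  }
  ref_fit <- matrix(frames$coords[reference_frame, fit_indices, ], ncol = 3)
  ref_lig <- matrix(frames$coords[reference_frame, ligand_indices, ], ncol = 3)
  vals <- vapply(seq_len(nf), function(i) {
    tr <- kabsch_superpose(matrix(frames$coords[i, fit_indices, ], ncol = 3),
                           ref_fit)
    lig <- apply_transform(matrix(frames$coords[i, ligand_indices, ], ncol = 3),
                           tr)
    sqrt(mean(rowSums((lig - ref_lig)^2)))
  }, numeric(1))
  structure(
    new_series_tbl(vals, label, frames$replica_id, "rmsd_tbl"),
    reference_frame = as.integer(reference_frame)
  )
}

#' Write a per-frame series to CSV
#'
#' Columns `replica_id`, `frame`, `label`, `value` — the exchange format
#' shared by torsion, distance and RMSD series.
#'
#' @param series A series tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  req <- c("replica_id", "frame", "label", "value")
  if (!all(req %in% names(series))) {
    abort("series must have columns replica_id, frame, label, value",
          class = "ligmode_invalid_input")
  }
  write.csv(series[, req], path, row.names = FALSE)
  invisible(path)
}
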
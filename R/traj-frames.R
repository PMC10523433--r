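#' Trajectory frames container
#'
#' Holds per-frame Cartesian coordinates (Angstrom) together with atom
#' metadata for one replica of a trajectory. Coordinates are stored as a
#' `frames x atoms x 3` array; atom metadata is a tibble with one row per
#' atom in file order. The atom order is identical across frames.
#'
#' @param atoms Tibble/data frame with columns `atom_name`, `residue_name`,
#'   `residue_id`, `chain_id`, `element` (one row per atom).
#' @param coords Numeric array `frames x atoms x 3`, in Angstrom. A single
#'   `atoms x 3` matrix is promoted to one frame.
#' @param replica_id Integer replica label carried into every exported table.
#' @param frame_stride_ns Time spacing between stored frames, in
#'   nanoseconds. Metadata only; no interpolation is ever done.
#' @return An object of class `traj_frames`.
#' @export
traj_frames <- function(atoms, coords, replica_id = 1L, frame_stride_ns = 1) {
  atoms <- as_tibble(atoms)
  req <- c("atom_name", "residue_name", "residue_id", "chain_id", "element")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0) {
    abort(paste0("atoms is missing column(s): ", paste(miss, collapse = ", ")),
          class = "ligmode_invalid_input")
  }
  if (is.matrix(coords)) coords <- array(coords, dim = c(1L, dim(coords)))
  if (!is.array(coords) || length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    abort("coords must be a frames x atoms x 3 array",
          class = "ligmode_invalid_input")
  }
  if (dim(coords)[1] < 1) {
    abort("trajectory must contain at least one frame",
          class = "ligmode_invalid_input")
  }
  if (dim(coords)[2] != nrow(atoms)) {
    abort(sprintf("coords has %d atoms but metadata has %d rows",
                  dim(coords)[2], nrow(atoms)),
          class = "ligmode_invalid_input")
  }
  if (!all(is.finite(coords))) {
    abort("coords contains non-finite values", class = "ligmode_invalid_input")
  }
  if (any(atoms$residue_id < 1)) {
    abort("residue_id must be >= 1", class = "ligmode_invalid_input")
  }
  if (any(!nzchar(atoms$atom_name))) {
    abort("atom_name must be nonempty", class = "ligmode_invalid_input")
  }
  key <- paste(atoms$residue_id, atoms$atom_name, atoms$chain_id)
  if (anyDuplicated(key)) {
    abort("(residue_id, atom_name, chain_id) must be unique within a frame",
          class = "ligmode_invalid_input")
  }
  structure(
    list(atoms = atoms, coords = coords,
         replica_id = as.integer(replica_id),
         frame_stride_ns = as.numeric(frame_stride_ns)),
    class = "traj_frames"
  )
}

#' @export
print.traj_frames <- function(x, ...) {
  cat(sprintf("<traj_frames> %d frame(s) x %d atoms, replica %d, stride %g ns\n",
              n_frames(x), n_atoms(x), x$replica_id, x$frame_stride_ns))
  cat("residues:",
      paste(unique(paste0(x$atoms$residue_name, x$atoms$residue_id)),
            collapse = " "), "\n")
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param frames A `traj_frames` object.
#' @return Integer count.
#' @export
n_frames <- function(frames) {
  stopifnot(inherits(frames, "traj_frames"))
  dim(frames$coords)[1]
}

#' @rdname n_frames
#' @export
n_atoms <- function(frames) {
  stopifnot(inherits(frames, "traj_frames"))
  dim(frames$coords)[2]
}

# internal: atoms x 3 coordinate matrix of one frame
frame_coords <- function(frames, i) {
  if (i < 1 || i > n_frames(frames)) {
    abort(sprintf("frame index %d out of range [1, %d]", i, n_frames(frames)),
          class = "ligmode_invalid_input")
  }
  matrix(frames$coords[i, , ], ncol = 3)
}
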
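#' Read a multi-model PDB file as trajectory frames
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a file without `MODEL`
#' records is read as a single frame. `ATOM` and `HETATM` records are
#' treated identically, so ligand heteroatoms participate in every
#' selection. Parsing is delegated to [bio3d::read.pdb()]; this wrapper
#' validates the per-model atom counts first so a malformed file fails
#' with the offending model named.
#'
#' @param path Path to a PDB file.
#' @param replica_id Replica label to attach to the frames.
#' @param frame_stride_ns Time spacing metadata, ns per stored frame.
#' @return A [traj_frames] object.
#' @seealso [write_multimodel_pdb()] for the inverse operation.
#' @export
read_multimodel_pdb <- function(path, replica_id = 1L, frame_stride_ns = 1) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "ligmode_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) {
    abort(paste0("no ATOM/HETATM records in ", path),
          class = "ligmode_empty_input")
  }
  model_starts <- grepl("^MODEL", lines)
  if (any(model_starts)) {
    model_of <- cumsum(model_starts)
    counts <- table(factor(model_of[is_atom],
                           levels = seq_len(sum(model_starts))))
    counts <- as.integer(counts)
    if (length(unique(counts)) > 1) {
      bad <- which(counts != counts[1])[1]
      abort(sprintf(
        "inconsistent atom counts between models: MODEL %d has %d atoms, MODEL 1 has %d",
        bad, counts[bad], counts[1]),
        class = "ligmode_parse_error")
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- tibble(
    atom_name    = pdb$atom$elety,
    residue_name = pdb$atom$resid,
    residue_id   = as.integer(pdb$atom$resno),
    chain_id     = ifelse(is.na(pdb$atom$chain), "", pdb$atom$chain),
    element      = ifelse(is.na(pdb$atom$elesy), "", pdb$atom$elesy)
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na_ <- nrow(atoms)
  coords <- aperm(array(t(xyz), dim = c(3, na_, nf)), c(3, 2, 1))
  traj_frames(atoms, coords, replica_id = replica_id,
              frame_stride_ns = frame_stride_ns)
}

#' Write trajectory frames as a multi-model PDB file
#'
#' One `MODEL` block per frame, fixed-column PDB format via
#' [bio3d::write.pdb()]. Coordinates survive a round trip through
#' [read_multimodel_pdb()] to within 0.001 Angstrom (the PDB column
#' precision); atom names, residue names/ids and chain ids round-trip
#' exactly.
#'
#' @param frames A [traj_frames] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(frames, path) {
  stopifnot(inherits(frames, "traj_frames"))
  if (n_frames(frames) < 1 || n_atoms(frames) < 1) {
    abort("cannot write an empty trajectory", class = "ligmode_invalid_input")
  }
  if (any(abs(frames$coords) >= 10000)) {
    abort("coordinates exceed PDB fixed-column width (|x| >= 10000 Angstrom)",
          class = "ligmode_format_error")
  }
  nf <- n_frames(frames)
  na_ <- n_atoms(frames)
  # bio3d xyz layout: one row per frame, x1 y1 z1 x2 y2 z2 ...
  xyz <- t(matrix(aperm(frames$coords, c(3, 2, 1)), ncol = nf))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = rep("ATOM", na_),
    resno = frames$atoms$residue_id,
    resid = frames$atoms$residue_name,
    eleno = seq_len(na_),
    elety = frames$atoms$atom_name,
    chain = ifelse(nzchar(frames$atoms$chain_id), frames$atoms$chain_id, " "),
    elesy = frames$atoms$element
  )
  invisible(path)
}

#' Read an XYZ trajectory file
#'
#' Standard chemical XYZ format: repeated blocks of an atom-count line, a
#' comment line, then `element x y z` lines. Blocks are concatenated in
#' file order as frames. XYZ carries no residue information, so residue
#' metadata is filled with a single placeholder residue; selections on
#' XYZ input must therefore address atoms positionally or by element.
#'
#' @inheritParams read_multimodel_pdb
#' @return A [traj_frames] object.
#' @export
read_xyz_trajectory <- function(path, replica_id = 1L, frame_stride_ns = 1) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "ligmode_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  # drop trailing blank lines only
  while (length(lines) > 0 && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0) {
    abort(paste0("empty XYZ file: ", path), class = "ligmode_empty_input")
  }
  frames_list <- list()
  elements <- NULL
  i <- 1L
  block <- 0L
  while (i <= length(lines)) {
    block <- block + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1) {
      abort(sprintf("XYZ block %d: invalid atom-count line '%s'",
                    block, lines[i]),
            class = "ligmode_parse_error")
    }
    if (i + 1 + nat > length(lines)) {
      abort(sprintf("XYZ block %d: count %d but only %d atom lines remain",
                    block, nat, length(lines) - i - 1),
            class = "ligmode_parse_error")
    }
    atom_lines <- lines[(i + 2):(i + 1 + nat)]
    toks <- strsplit(trimws(atom_lines), "[[:space:]]+")
    bad <- which(vapply(toks, length, 1L) < 4)
    if (length(bad) > 0) {
      abort(sprintf("XYZ block %d: malformed atom line %d", block, bad[1]),
            class = "ligmode_parse_error")
    }
    el <- vapply(toks, `[[`, "", 1)
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    if (any(!is.finite(xyz))) {
      abort(sprintf("XYZ block %d: non-numeric coordinates", block),
            class = "ligmode_parse_error")
    }
    if (is.null(elements)) {
      elements <- el
    } else if (length(el) != length(elements) || any(el != elements)) {
      abort(sprintf("XYZ block %d: atoms differ from block 1", block),
            class = "ligmode_parse_error")
    }
    frames_list[[block]] <- xyz
    i <- i + 2L + nat
  }
  nat <- length(elements)
  coords <- array(0, dim = c(length(frames_list), nat, 3))
  for (k in seq_along(frames_list)) coords[k, , ] <- frames_list[[k]]
  atoms <- tibble(
    atom_name = paste0(elements, seq_len(nat)),
    residue_name = "UNK",
    residue_id = 1L,
    chain_id = "",
    element = elements
  )
  traj_frames(atoms, coords, replica_id = replica_id,
              frame_stride_ns = frame_stride_ns)
}
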
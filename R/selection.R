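#' Selection specification
#'
#' Maps the names the analysis speaks in — Ballesteros-Weinstein (BW)
#' positions such as "6.51", the ligand chain dihedral quartet, the
#' terminal chain carbons, the aromatic ring atoms — onto concrete
#' residues and atom names of a particular system. The BW mapping is a
#' supplied table, not computed by alignment.
#'
#' @param bw_map Data frame with columns `bw_position` (e.g. "6.51"),
#'   `residue_id`, `residue_name`.
#' @param ligand_quartet Character vector of exactly 4 distinct atom
#'   names defining the chain dihedral, in 1-2-3-4 order.
#' @param ligand_terminal_atoms One or more ligand atom names treated as
#'   the terminal methyl (or dimethyl) carbons for distance analysis.
#' @param ring_atoms At least 3 atom names spanning the aromatic ring of
#'   the residue at `ring_bw`.
#' @param receptor_fit_atoms Atom-name filter for superposition;
#'   defaults to backbone alpha-carbons (`"CA"`).
#' @param ligand_resname Residue name of the ligand (default `"LIG"`).
#' @param ring_bw BW position carrying the aromatic ring (default
#'   `"3.36"`, the toggle-switch phenylalanine).
#' @return An object of class `selection_spec`.
#' @export
selection_spec <- function(bw_map, ligand_quartet, ligand_terminal_atoms,
                           ring_atoms, receptor_fit_atoms = "CA",
                           ligand_resname = "LIG", ring_bw = "3.36") {
  bw_map <- as_tibble(bw_map)
  req <- c("bw_position", "residue_id", "residue_name")
  if (!all(req %in% names(bw_map))) {
    abort("bw_map needs columns bw_position, residue_id, residue_name",
          class = "ligmode_invalid_input")
  }
  bw_map$bw_position <- as.character(bw_map$bw_position)
  ligand_quartet <- as.character(ligand_quartet)
  if (length(ligand_quartet) != 4 || anyDuplicated(ligand_quartet)) {
    abort("ligand_quartet must be exactly 4 distinct atom names",
          class = "ligmode_invalid_input")
  }
  if (length(ligand_terminal_atoms) < 1) {
    abort("ligand_terminal_atoms must name at least one atom",
          class = "ligmode_invalid_input")
  }
  if (length(ring_atoms) < 3) {
    abort("ring_atoms must name at least 3 atoms",
          class = "ligmode_invalid_input")
  }
  structure(
    list(bw_map = bw_map,
         ligand_quartet = ligand_quartet,
         ligand_terminal_atoms = as.character(ligand_terminal_atoms),
         ring_atoms = as.character(ring_atoms),
         receptor_fit_atoms = as.character(receptor_fit_atoms),
         ligand_resname = as.character(ligand_resname),
         ring_bw = as.character(ring_bw)),
    class = "selection_spec"
  )
}

#' Read / write a selection specification (YAML or JSON)
#'
#' The on-disk form mirrors the constructor arguments; the format is
#' chosen from the file extension (`.yml`/`.yaml` vs `.json`).
#'
#' @param path File path.
#' @return For the reader, a [selection_spec]; the writer returns `path`
#'   invisibly.
#' @export
read_selection_spec <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "ligmode_io_error")
  }
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  bw <- x$bw_map
  if (is.list(bw) && !is.data.frame(bw)) {
    bw <- purrr::map_dfr(bw, as_tibble)
  }
  selection_spec(
    bw_map = bw,
    ligand_quartet = unlist(x$ligand_quartet),
    ligand_terminal_atoms = unlist(x$ligand_terminal_atoms),
    ring_atoms = unlist(x$ring_atoms),
    receptor_fit_atoms = unlist(x$receptor_fit_atoms) %||% "CA",
    ligand_resname = x$ligand_resname %||% "LIG",
    ring_bw = x$ring_bw %||% "3.36"
  )
}

#' @rdname read_selection_spec
#' @param spec A [selection_spec] object.
#' @export
write_selection_spec <- function(spec, path) {
  stopifnot(inherits(spec, "selection_spec"))
  x <- list(
    bw_map = lapply(seq_len(nrow(spec$bw_map)), function(i)
      as.list(spec$bw_map[i, ])),
    ligand_quartet = spec$ligand_quartet,
    ligand_terminal_atoms = spec$ligand_terminal_atoms,
    ring_atoms = spec$ring_atoms,
    receptor_fit_atoms = spec$receptor_fit_atoms,
    ligand_resname = spec$ligand_resname,
    ring_bw = spec$ring_bw
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

# chi1 gamma atom by residue type: first side-chain gamma atom present.
# Val is beta-branched so its chi1 reference is CG1; Ile likewise.
chi1_gamma <- c(
  VAL = "CG1", ILE = "CG1", THR = "OG1", SER = "OG", CYS = "SG"
)

#' Resolve a named selection to atom indices
#'
#' Turns a role or a Ballesteros-Weinstein position into row indices of
#' `frames$atoms` (valid for every frame, since atom order is constant).
#' Supported values of `what`:
#'
#' * `"ligand_quartet"` — the 4 chain-dihedral atoms, in 1-2-3-4 order;
#' * `"ligand_terminal_atoms"` — terminal methyl/dimethyl carbons;
#' * `"ring_atoms"` — aromatic ring atoms of the residue at `ring_bw`;
#' * `"receptor_fit_atoms"` — all receptor atoms matching the fit filter
#'   (ligand residue excluded);
#' * a BW position, e.g. `"6.51"` — the chi1 quartet N, CA, CB and the
#'   first gamma atom of that residue (CG for Leu/Phe/Trp, CG1 for Val);
#' * a BW position with role suffix, e.g. `"6.51:side_carbons"` — the
#'   distal side-chain carbons (gamma and delta) used for contact
#'   distances, or `"6.51:chi1"` (same as the bare position).
#'
#' @param frames A [traj_frames] object.
#' @param spec A [selection_spec].
#' @param what Role keyword or BW position (see Details).
#' @return Integer vector of atom indices, in a deterministic order
#'   (quartet order for dihedrals, file order otherwise).
#' @export
resolve_selection <- function(frames, spec, what) {
  stopifnot(inherits(frames, "traj_frames"), inherits(spec, "selection_spec"))
  atoms <- frames$atoms
  find_atom <- function(resid_sel, name, context) {
    idx <- which(resid_sel & atoms$atom_name == name)
    if (length(idx) == 0) {
      abort(sprintf("atom '%s' not found while resolving %s (searched %d atoms)",
                    name, context, sum(resid_sel)),
            class = "ligmode_resolution_error")
    }
    idx[1]
  }
  bw_residue <- function(bw) {
    row <- spec$bw_map[spec$bw_map$bw_position == bw, ]
    if (nrow(row) == 0) {
      abort(sprintf("BW position '%s' not present in bw_map (has: %s)",
                    bw, paste(spec$bw_map$bw_position, collapse = ", ")),
            class = "ligmode_resolution_error")
    }
    row[1, ]
  }
  is_lig <- atoms$residue_name == spec$ligand_resname

  if (what == "ligand_quartet") {
    return(vapply(spec$ligand_quartet, function(nm)
      find_atom(is_lig, nm, "ligand_quartet"), 1L, USE.NAMES = FALSE))
  }
  if (what == "ligand_terminal_atoms") {
    return(vapply(spec$ligand_terminal_atoms, function(nm)
      find_atom(is_lig, nm, "ligand_terminal_atoms"), 1L, USE.NAMES = FALSE))
  }
  if (what == "ring_atoms") {
    res <- bw_residue(spec$ring_bw)
    in_res <- atoms$residue_id == res$residue_id & !is_lig
    return(vapply(spec$ring_atoms, function(nm)
      find_atom(in_res, nm, paste0("ring_atoms@", spec$ring_bw)),
      1L, USE.NAMES = FALSE))
  }
  if (what == "receptor_fit_atoms") {
    idx <- which(!is_lig & atoms$atom_name %in% spec$receptor_fit_atoms)
    if (length(idx) == 0) {
      abort(sprintf("no receptor atoms match fit filter [%s]",
                    paste(spec$receptor_fit_atoms, collapse = ", ")),
            class = "ligmode_resolution_error")
    }
    return(idx)
  }

  # BW position, optionally with a role suffix
  parts <- strsplit(what, ":", fixed = TRUE)[[1]]
  bw <- parts[1]
  role <- if (length(parts) > 1) parts[2] else "chi1"
  res <- bw_residue(bw)
  in_res <- atoms$residue_id == res$residue_id &
    atoms$residue_name == res$residue_name & !is_lig
  if (!any(in_res)) {
    abort(sprintf("residue %s%d for BW %s not found in trajectory",
                  res$residue_name, res$residue_id, bw),
          class = "ligmode_resolution_error")
  }
  if (role == "chi1") {
    gname <- unname(chi1_gamma[res$residue_name])
    if (is.na(gname)) gname <- "CG"
    return(vapply(c("N", "CA", "CB", gname), function(nm)
      find_atom(in_res, nm, paste0("chi1@", bw)), 1L, USE.NAMES = FALSE))
  }
  if (role == "side_carbons") {
    idx <- which(in_res &
                   grepl("^C[GD][0-9]?$", atoms$atom_name))
    if (length(idx) == 0) {
      abort(sprintf("no gamma/delta carbons found for BW %s", bw),
            class = "ligmode_resolution_error")
    }
    return(idx)
  }
  abort(sprintf("unknown selection role '%s'", role),
        class = "ligmode_resolution_error")
}
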
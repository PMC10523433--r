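make_pdb_text <- function(models) {
  # models: list of data frames with name, resn, resi, chain, x, y, z
  out <- character(0)
  for (m in seq_along(models)) {
    out <- c(out, sprintf("MODEL     %4d", m))
    df <- models[[m]]
    for (i in seq_len(nrow(df))) {
      out <- c(out, sprintf(
        "%-6s%5d %-4s%-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        df$rec[i], i, df$name[i], df$resn[i], df$chain[i], df$resi[i],
        df$x[i], df$y[i], df$z[i], df$el[i]))
    }
    out <- c(out, "ENDMDL")
  }
  c(out, "END")
}

five_atoms <- data.frame(
  rec = c("ATOM", "ATOM", "ATOM", "HETATM", "HETATM"),
  name = c("N", "CA", "CB", "C1", "C2"),
  resn = c("LEU", "LEU", "LEU", "LIG", "LIG"),
  chain = c("A", "A", "A", "L", "L"),
  resi = c(351L, 351L, 351L, 900L, 900L),
  x = c(1.1, 2.2, 3.3, 4.4, 5.5), y = 0.5, z = -1.25,
  el = c("N", "C", "C", "C", "C")
)

test_that("multi-model PDB reading counts frames and atoms, HETATM included", {
  path <- withr::local_tempfile(fileext = ".pdb")
  m2 <- five_atoms
  m2$x <- m2$x + 1
  writeLines(make_pdb_text(list(five_atoms, m2)), path)
  fr <- read_multimodel_pdb(path)
  expect_equal(n_frames(fr), 2)
  expect_equal(n_atoms(fr), 5)
  expect_equal(fr$atoms$atom_name, c("N", "CA", "CB", "C1", "C2"))
  expect_equal(fr$coords[1, , 1], five_atoms$x)
  expect_equal(fr$coords[2, , 1], five_atoms$x + 1)

  # single model, no MODEL records
  path1 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(make_pdb_text(list(five_atoms))[-c(1, 7)], path1)
  expect_equal(n_frames(read_multimodel_pdb(path1)), 1)
})

test_that("PDB parse errors name the offending model and empty input fails", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(make_pdb_text(list(five_atoms, five_atoms[-3, ])), path)
  expect_error(read_multimodel_pdb(path), "MODEL 2",
               class = "ligmode_parse_error")

  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), empty)
  expect_error(read_multimodel_pdb(empty), class = "ligmode_empty_input")
})

test_that("PDB write -> read round-trips metadata exactly and coords to 0.001 A", {
  set.seed(11)
  atoms <- tibble::tibble(
    atom_name = c("N", "CA", "CB", "CG", "C1", "C2", "C3", "C4", "O1", "CZ"),
    residue_name = c(rep("LEU", 4), rep("LIG", 5), "PHE"),
    residue_id = c(rep(351L, 4), rep(900L, 5), 336L),
    chain_id = c(rep("A", 4), rep("L", 5), "A"),
    element = c("N", rep("C", 7), "O", "C")
  )
  coords <- array(round(runif(2 * 10 * 3, -50, 50), 3), dim = c(2, 10, 3))
  fr <- traj_frames(atoms, coords, replica_id = 2L)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(fr, path)
  fr2 <- read_multimodel_pdb(path, replica_id = 2L)
  expect_identical(fr2$atoms$atom_name, fr$atoms$atom_name)
  expect_identical(fr2$atoms$residue_name, fr$atoms$residue_name)
  expect_identical(fr2$atoms$residue_id, fr$atoms$residue_id)
  expect_identical(fr2$atoms$chain_id, fr$atoms$chain_id)
  expect_lt(max(abs(fr2$coords - fr$coords)), 0.001 + 1e-12)
})

test_that("PDB writing rejects oversized coordinates and empty frames", {
  atoms <- tibble::tibble(atom_name = c("C1", "C2", "C3"),
                          residue_name = "LIG", residue_id = 1L,
                          chain_id = "L", element = "C")
  coords <- array(0, dim = c(1, 3, 3))
  coords[1, 1, 1] <- 123456
  fr <- traj_frames(atoms, coords)
  expect_error(write_multimodel_pdb(fr, withr::local_tempfile()),
               class = "ligmode_format_error")
  expect_error(traj_frames(atoms, array(0, dim = c(0, 3, 3))),
               class = "ligmode_invalid_input")
})

test_that("XYZ trajectories parse blocks in order and report malformed blocks", {
  path <- withr::local_tempfile(fileext = ".xyz")
  block <- function(shift) {
    c("4", paste("frame shift", shift),
      sprintf("C %.3f 0.0 0.0", 0.0 + shift),
      sprintf("C %.3f 0.0 0.0", 1.5 + shift),
      sprintf("C %.3f 1.4 0.0", 2.1 + shift),
      sprintf("O %.3f 1.5 1.0", 2.5 + shift))
  }
  writeLines(c(block(0), block(1), block(2)), path)
  fr <- read_xyz_trajectory(path)
  expect_equal(n_frames(fr), 3)
  expect_equal(n_atoms(fr), 4)
  expect_equal(fr$atoms$element, c("C", "C", "C", "O"))
  expect_equal(fr$coords[2, 1, 1], 1.0)

  empty <- withr::local_tempfile(fileext = ".xyz")
  writeLines(character(0), empty)
  expect_error(read_xyz_trajectory(empty), class = "ligmode_empty_input")

  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("4", "comment", "C 0 0 0", "C 1 0 0", "C 2 0 0"), bad)
  expect_error(read_xyz_trajectory(bad), "block 1",
               class = "ligmode_parse_error")
})

test_that("selections resolve deterministically by role and BW position", {
  p <- synthetic_params(n_frames = 3, n_replicas = 1, seed = 1)
  built <- series_to_coordinates(simulate_series(p))
  fr <- built$frames[[1]]
  spec <- built$selection

  q <- resolve_selection(fr, spec, "ligand_quartet")
  expect_length(q, 4)
  expect_equal(fr$atoms$atom_name[q], c("C1", "C2", "C3", "C4"))

  chi1 <- resolve_selection(fr, spec, "6.51")
  expect_equal(fr$atoms$atom_name[chi1], c("N", "CA", "CB", "CG"))
  expect_equal(unique(fr$atoms$residue_id[chi1]), 351L)
  expect_identical(chi1, resolve_selection(fr, spec, "6.51:chi1"))
  # repeated calls are identical (pure function of metadata + spec)
  expect_identical(chi1, resolve_selection(fr, spec, "6.51"))

  ring <- resolve_selection(fr, spec, "ring_atoms")
  expect_length(ring, 6)
  expect_equal(unique(fr$atoms$residue_id[ring]), 336L)

  fit <- resolve_selection(fr, spec, "receptor_fit_atoms")
  expect_true(all(fr$atoms$atom_name[fit] == "CA"))
  expect_false(any(fr$atoms$residue_name[fit] == "LIG"))

  side <- resolve_selection(fr, spec, "6.51:side_carbons")
  expect_true(all(grepl("^C[GD]", fr$atoms$atom_name[side])))

  expect_error(resolve_selection(fr, spec, "9.99"), "9.99",
               class = "ligmode_resolution_error")
})

test_that("chi1 quartet uses CG1 for beta-branched valine", {
  atoms <- tibble::tibble(
    atom_name = c("N", "CA", "CB", "CG1", "CG2"),
    residue_name = "VAL", residue_id = 251L, chain_id = "A", element = "C"
  )
  fr <- traj_frames(atoms, array(rnorm(15), dim = c(1, 5, 3)))
  spec <- selection_spec(
    bw_map = data.frame(bw_position = "6.51", residue_id = 251L,
                        residue_name = "VAL"),
    ligand_quartet = c("C1", "C2", "C3", "C4"),
    ligand_terminal_atoms = "C4",
    ring_atoms = c("CG", "CD1", "CD2")
  )
  chi1 <- resolve_selection(fr, spec, "6.51")
  expect_equal(fr$atoms$atom_name[chi1], c("N", "CA", "CB", "CG1"))
})

test_that("selection specs round-trip through YAML and JSON", {
  p <- synthetic_params(n_frames = 2, n_replicas = 1, seed = 1)
  spec <- series_to_coordinates(simulate_series(p))$selection
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_selection_spec(spec, path)
    spec2 <- read_selection_spec(path)
    expect_equal(spec2$ligand_quartet, spec$ligand_quartet)
    expect_equal(spec2$ring_atoms, spec$ring_atoms)
    expect_equal(as.data.frame(spec2$bw_map), as.data.frame(spec$bw_map))
    expect_equal(spec2$ligand_resname, spec$ligand_resname)
  }
})
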
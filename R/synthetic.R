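#' Parameters of the synthetic trajectory generator
#'
#' Defines a coupled two-state system emulating the statistical structure
#' of cannabinoid-receptor MD trajectories: the ligand chain dihedral
#' switches between a minus-anticlinal well near -90 degrees (L-shape)
#' and a plus-anticlinal well near +90 degrees (I-shape) under a
#' first-order Markov chain; the receptor chi1 rotamer tracks the chain
#' state with probability `p_couple` per frame (t with the L-shape,
#' gauche+ with the I-shape) and otherwise resamples from its marginal;
#' angles are emitted von Mises around the state centre and the
#' ligand-to-ring-centroid gate distance Gaussian around a
#' state-dependent mean straddling the 5 Angstrom contact criterion.
#'
#' @param n_frames Frames per replica (>= 1).
#' @param n_replicas Number of replicas; replica `r` uses seed
#'   `seed + r - 1`.
#' @param seed Base random seed (mandatory for reproducibility).
#' @param receptor_variant `"CB1"` (chain switching enabled) or `"CB2"`
#'   (chain locked in the minus-anticlinal state). Chooses the default
#'   `chain_transition`.
#' @param chain_transition 2 x 2 row-stochastic matrix over
#'   (MINUS_AC, PLUS_AC); rows sum to 1. Defaults: symmetric with
#'   per-frame stay probability 0.99 for `"CB1"`, absorbing MINUS_AC for
#'   `"CB2"`.
#' @param p_couple Probability in \[0, 1\] that the rotamer copies the
#'   chain state in a given frame (default 0.9).
#' @param chain_centers Named degrees of the chain wells
#'   (default MINUS_AC = -90, PLUS_AC = +90).
#' @param rotamer_centers Named degrees of the rotamer wells
#'   (default T = 180, GPLUS = -60).
#' @param kappa von Mises concentration of the angular emissions
#'   (default 8, about 20 degrees circular standard deviation).
#' @param distance_mean Named Angstrom means of the gate distance per
#'   chain state (default MINUS_AC = 7.0, PLUS_AC = 4.0).
#' @param distance_sd Gaussian spread of the gate distance (default 0.5).
#' @return A validated `synthetic_params` object.
#' @export
synthetic_params <- function(n_frames = 1000L, n_replicas = 3L, seed = 1L,
                             receptor_variant = c("CB1", "CB2"),
                             chain_transition = NULL,
                             p_couple = 0.9,
                             chain_centers = c(MINUS_AC = -90, PLUS_AC = 90),
                             rotamer_centers = c(T = 180, GPLUS = -60),
                             kappa = 8,
                             distance_mean = c(MINUS_AC = 7.0, PLUS_AC = 4.0),
                             distance_sd = 0.5) {
  receptor_variant <- match.arg(receptor_variant)
  if (n_frames < 1) {
    abort("n_frames must be >= 1", class = "ligmode_parameter_error")
  }
  if (n_replicas < 1) {
    abort("n_replicas must be >= 1", class = "ligmode_parameter_error")
  }
  if (is.null(chain_transition)) {
    chain_transition <- if (receptor_variant == "CB1") {
      matrix(c(0.99, 0.01, 0.01, 0.99), 2, byrow = TRUE)
    } else {
      matrix(c(1, 0, 1, 0), 2, byrow = TRUE)
    }
  }
  chain_transition <- as.matrix(chain_transition)
  if (!all(dim(chain_transition) == c(2, 2)) ||
      any(chain_transition < 0) ||
      any(abs(rowSums(chain_transition) - 1) > 1e-9)) {
    abort("chain_transition must be a 2x2 row-stochastic matrix",
          class = "ligmode_parameter_error")
  }
  dimnames(chain_transition) <- list(chain_mode_levels, chain_mode_levels)
  if (p_couple < 0 || p_couple > 1) {
    abort("p_couple must be in [0, 1]", class = "ligmode_parameter_error")
  }
  if (kappa <= 0) abort("kappa must be > 0", class = "ligmode_parameter_error")
  if (distance_sd <= 0) {
    abort("distance_sd must be > 0", class = "ligmode_parameter_error")
  }
  for (nm in list(chain_centers, rotamer_centers)) {
    if (any(nm <= -180 | nm > 180)) {
      abort("state centers must lie in (-180, 180]",
            class = "ligmode_parameter_error")
    }
  }
  if (!all(chain_mode_levels %in% names(chain_centers)) ||
      !all(chain_mode_levels %in% names(distance_mean)) ||
      !all(c("T", "GPLUS") %in% names(rotamer_centers))) {
    abort("chain_centers/distance_mean need MINUS_AC and PLUS_AC; rotamer_centers need T and GPLUS",
          class = "ligmode_parameter_error")
  }
  structure(
    list(n_frames = as.integer(n_frames), n_replicas = as.integer(n_replicas),
         seed = as.integer(seed), receptor_variant = receptor_variant,
         chain_transition = chain_transition, p_couple = p_couple,
         chain_centers = chain_centers, rotamer_centers = rotamer_centers,
         kappa = kappa, distance_mean = distance_mean,
         distance_sd = distance_sd),
    class = "synthetic_params"
  )
}

# stationary distribution of a 2x2 chain; for a degenerate/non-unique
# chain (identity) the convention is to start and stay in state 1
chain_stationary <- function(p) {
  a <- p[1, 2]  # MINUS -> PLUS
  b <- p[2, 1]  # PLUS -> MINUS
  if (a + b < 1e-12) return(c(1, 0))
  c(b, a) / (a + b)
}

#' Simulate coupled chain/rotamer series
#'
#' Runs the generator defined by a [synthetic_params] object and returns
#' one tidy row per frame across all replicas. Identical parameters
#' (including seed) give identical output.
#'
#' @param params A [synthetic_params] object.
#' @return A tibble (`synthetic_series`) with columns `replica_id`,
#'   `frame`, `chain_state`, `rotamer_state` (the true labels),
#'   `chain_angle`, `chi1_angle` (degrees) and `distance` (Angstrom);
#'   the generating parameters are attached as attribute `params`.
#' @export
simulate_series <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  pim <- chain_stationary(params$chain_transition)
  reps <- lapply(seq_len(params$n_replicas), function(r) {
    set.seed(params$seed + r - 1L)
    n <- params$n_frames
    # chain: first-order Markov walk started from the stationary law
    s <- integer(n)
    s[1] <- if (runif(1) < pim[1]) 1L else 2L
    if (n > 1) {
      u <- runif(n - 1)
      for (t in 2:n) {
        s[t] <- if (u[t - 1] < params$chain_transition[s[t - 1], 1]) 1L else 2L
      }
    }
    chain_state <- chain_mode_levels[s]
    # rotamer: copies the chain state w.p. p_couple, else its marginal
    copy <- runif(n) < params$p_couple
    free <- ifelse(runif(n) < pim[1], "T", "GPLUS")
    rotamer_state <- ifelse(copy, ifelse(chain_state == "MINUS_AC",
                                         "T", "GPLUS"), free)
    # angular and distance emissions conditioned on the hidden states
    chain_angle <- numeric(n)
    for (st in chain_mode_levels) {
      k <- which(chain_state == st)
      if (length(k)) {
        chain_angle[k] <- rvonmises(length(k), params$chain_centers[[st]],
                                    params$kappa)
      }
    }
    chi1_angle <- numeric(n)
    for (st in c("T", "GPLUS")) {
      k <- which(rotamer_state == st)
      if (length(k)) {
        chi1_angle[k] <- rvonmises(length(k), params$rotamer_centers[[st]],
                                   params$kappa)
      }
    }
    distance <- rnorm(n, params$distance_mean[chain_state], params$distance_sd)
    # gate distances are physical separations; redraw the (practically
    # impossible at default parameters) negative tail
    for (it in 1:10) {
      bad <- which(distance <= 0)
      if (!length(bad)) break
      distance[bad] <- rnorm(length(bad), params$distance_mean[chain_state[bad]],
                             params$distance_sd)
    }
    if (any(distance <= 0)) {
      abort("distance emission parameters produce non-physical distances",
            class = "ligmode_parameter_error")
    }
    tibble(
      replica_id = r, frame = seq_len(n),
      chain_state = factor(chain_state, levels = chain_mode_levels),
      rotamer_state = factor(rotamer_state, levels = rotamer_levels),
      chain_angle = chain_angle, chi1_angle = chi1_angle,
      distance = distance
    )
  })
  out <- dplyr::bind_rows(reps)
  structure(out, params = params,
            class = c("synthetic_series", class(tibble())))
}

# fixed scaffold coordinates shared by every synthetic frame
synthetic_scaffold <- function() {
  list(
    # four non-coplanar alpha-carbons: a stable superposition frame
    gly_ca = rbind(c(0, 0, 0), c(3.8, 0, 0), c(5.7, 3.3, 0), c(5.7, 3.3, 3.8)),
    # Leu 6.51 backbone (N, CA, CB fixed; CG placed per frame by chi1)
    leu_n  = c(12, 0, 0),
    leu_ca = c(13.45, 0.5, 0),
    leu_cb = c(14.3, -0.5, 0.85),
    # ligand chain atoms 1-3 fixed; atom 4 placed per frame
    lig_c1 = c(20, 5, 0),
    lig_c2 = c(21.53, 5, 0),
    lig_c3 = NULL  # derived below
  )
}

#' Realise a synthetic series as 3-D trajectory frames
#'
#' Builds, for every frame, a minimal coordinate system whose geometry
#' reproduces the simulated series exactly: a 4-carbon ligand chain with
#' 1.53 Angstrom bonds and 111-degree angles whose 1-2-3-4 torsion
#' equals the chain angle; a residue-6.51 side-chain quartet (N, CA, CB,
#' CG) realising the chi1 angle; a 6-atom regular phenylalanine ring
#' placed so that the terminal chain carbon-to-ring-centroid distance
#' equals the simulated gate distance; and four static alpha-carbons as
#' a superposition scaffold.
#'
#' @param series A `synthetic_series` tibble (one or more replicas).
#' @return A list with `frames` (list of [traj_frames], one per
#'   replica), `selection` (the matching [selection_spec]) and `truth`
#'   (tibble of true per-frame state labels).
#' @export
series_to_coordinates <- function(series) {
  if (!all(c("replica_id", "chain_angle", "chi1_angle", "distance") %in%
           names(series))) {
    abort("series must come from simulate_series()",
          class = "ligmode_invalid_input")
  }
  if (any(series$distance <= 0)) {
    abort("distances must be positive to be realisable as geometry",
          class = "ligmode_parameter_error")
  }
  sc <- synthetic_scaffold()
  # ligand C3 from C1-C2 at 111 degrees in the xy-plane
  sc$lig_c3 <- zmat_place(c(sc$lig_c1[1], sc$lig_c1[2] + 1, sc$lig_c1[3]),
                          sc$lig_c1, sc$lig_c2, 1.53, 111, 0)
  ring_offsets <- t(vapply(0:5, function(k) {
    th <- deg2rad(60 * k)
    1.39 * c(cos(th), sin(th), 0)
  }, numeric(3)))
  atoms <- tibble(
    atom_name = c("CA", "CA", "CA", "CA",
                  "N", "CA", "CB", "CG",
                  "CG", "CD1", "CE1", "CZ", "CE2", "CD2",
                  "C1", "C2", "C3", "C4"),
    residue_name = c(rep("GLY", 4), rep("LEU", 4), rep("PHE", 6),
                     rep("LIG", 4)),
    residue_id = c(1:4, rep(351L, 4), rep(336L, 6), rep(900L, 4)),
    chain_id = c(rep("A", 14), rep("L", 4)),
    element = c(rep("C", 4), "N", rep("C", 13))
  )
  per_replica <- split(as_tibble(series), series$replica_id)
  frames_list <- lapply(per_replica, function(df) {
    n <- nrow(df)
    coords <- array(0, dim = c(n, nrow(atoms), 3))
    for (i in seq_len(n)) {
      lig_c4 <- zmat_place(sc$lig_c1, sc$lig_c2, sc$lig_c3,
                           1.53, 111, df$chain_angle[i])
      leu_cg <- zmat_place(sc$leu_n, sc$leu_ca, sc$leu_cb,
                           1.53, 111, df$chi1_angle[i])
      ring_center <- lig_c4 + c(0, 0, df$distance[i])
      ring <- sweep(ring_offsets, 2, ring_center, "+")
      coords[i, , ] <- rbind(
        sc$gly_ca,
        sc$leu_n, sc$leu_ca, sc$leu_cb, leu_cg,
        ring,
        sc$lig_c1, sc$lig_c2, sc$lig_c3, lig_c4
      )
    }
    traj_frames(atoms, coords, replica_id = df$replica_id[1])
  })
  spec <- selection_spec(
    bw_map = tibble(bw_position = c("3.36", "6.51"),
                    residue_id = c(336L, 351L),
                    residue_name = c("PHE", "LEU")),
    ligand_quartet = c("C1", "C2", "C3", "C4"),
    ligand_terminal_atoms = "C4",
    ring_atoms = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
    receptor_fit_atoms = "CA",
    ligand_resname = "LIG",
    ring_bw = "3.36"
  )
  truth <- as_tibble(series)[, c("replica_id", "frame",
                                 "chain_state", "rotamer_state")]
  list(frames = unname(frames_list), selection = spec, truth = truth)
}

#' Write a complete synthetic dataset to disk
#'
#' Simulates, realises coordinates and writes one multi-model PDB per
#' replica (`traj_rep<r>.pdb`), the ground-truth labels
#' (`truth.csv`: replica_id, frame, chain_state, rotamer_state) and the
#' matching selection config (`selection.yaml`). Rerunning with the same
#' parameters reproduces identical files.
#'
#' @param params A [synthetic_params] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the generated `series` and the file
#'   paths (`pdb`, `truth`, `selection`).
#' @export
write_synthetic_dataset <- function(params, dir) {
  stopifnot(inherits(params, "synthetic_params"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  series <- simulate_series(params)
  built <- series_to_coordinates(series)
  pdb_paths <- vapply(built$frames, function(fr) {
    p <- file.path(dir, sprintf("traj_rep%d.pdb", fr$replica_id))
    write_multimodel_pdb(fr, p)
    p
  }, "")
  truth_path <- file.path(dir, "truth.csv")
  write.csv(built$truth, truth_path, row.names = FALSE)
  sel_path <- file.path(dir, "selection.yaml")
  write_selection_spec(built$selection, sel_path)
  invisible(list(series = series, pdb = pdb_paths, truth = truth_path,
                 selection = sel_path))
}
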
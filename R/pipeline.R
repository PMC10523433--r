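analysis_toggles <- c("rmsd", "chain_mode", "rotamer", "distances", "coupling")

#' Run the full trajectory analysis from a config
#'
#' Drives the whole pipeline over one or more replicas: per replica it
#' computes the requested series (ligand chain torsion and binding-mode
#' states, residue chi1 and rotamer states, receptor-superposed ligand
#' RMSD, terminal-carbon-to-ring-centroid distances), then aggregates
#' state summaries, the chain-mode heatmap matrix, circular histograms
#' and the chain/rotamer coupling summary with distance gating. Results
#' are returned and, when `output_dir` is set, written as CSV/JSON.
#'
#' Statistics are reported both per replica and pooled (frames of all
#' replicas concatenated).
#'
#' @param config A named list, or path to a YAML file, with fields:
#'   `replicas` (character vector of multi-model PDB paths, one per
#'   replica), `selection` (path to a selection config, or a
#'   [selection_spec]), `analyses` (subset of `"rmsd"`, `"chain_mode"`,
#'   `"rotamer"`, `"distances"`, `"coupling"`),
#'   `threshold` (gate distance, default 5), `bins` (histogram bins,
#'   default 72), `downsample` (heatmap window, default 1),
#'   `chi1_bw` (BW position of the coupling residue, default "6.51"),
#'   `reference_frame` (RMSD reference, default 1), `output_dir`
#'   (optional; results written when present).
#' @return Invisibly, a list of computed objects (`torsions`, `states`,
#'   `rmsd`, `distances`, `summaries`, `coupling`, `heatmap`,
#'   `histograms`, `files`).
#' @export
run_analysis <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort("config must be a list or a YAML path", class = "ligmode_config_error")
  }
  analyses <- unlist(config$analyses) %||% character(0)
  bad <- setdiff(analyses, analysis_toggles)
  if (length(bad) > 0) {
    abort(paste0("unknown analyses: ", paste(bad, collapse = ", ")),
          class = "ligmode_config_error")
  }
  if (length(analyses) == 0) {
    abort("no analyses selected", class = "ligmode_config_error")
  }
  paths <- unlist(config$replicas)
  if (length(paths) < 1) {
    abort("config$replicas must list at least one trajectory",
          class = "ligmode_config_error")
  }
  spec <- config$selection
  if (is.character(spec)) spec <- read_selection_spec(spec)
  if (!inherits(spec, "selection_spec")) {
    abort("config$selection must be a selection_spec or a path",
          class = "ligmode_config_error")
  }
  threshold <- config$threshold %||% 5
  bins <- config$bins %||% 72
  downsample <- config$downsample %||% 1
  chi1_bw <- config$chi1_bw %||% "6.51"
  reference_frame <- config$reference_frame %||% 1
  out_dir <- config$output_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  needs_chain <- any(c("chain_mode", "coupling", "distances") %in% analyses)
  needs_rot <- any(c("rotamer", "coupling") %in% analyses)

  res <- list(torsions = list(), states = list(), rmsd = list(),
              distances = list(), files = character(0))
  emit <- function(obj, writer, name) {
    if (!is.null(out_dir)) {
      p <- file.path(out_dir, name)
      writer(obj, p)
      res$files <<- c(res$files, p)
    }
  }

  for (r in seq_along(paths)) {
    fr <- read_multimodel_pdb(paths[r], replica_id = r)
    if (needs_chain) {
      q <- resolve_selection(fr, spec, "ligand_quartet")
      ts <- torsion_series(fr, q, label = "chain_dihedral")
      res$torsions$chain[[r]] <- ts
      res$states$chain[[r]] <- classify_chain_mode(ts)
      emit(ts, write_series_csv, sprintf("chain_torsion_rep%d.csv", r))
    }
    if (needs_rot) {
      q <- resolve_selection(fr, spec, chi1_bw)
      ts <- torsion_series(fr, q, label = paste0("chi1_", chi1_bw))
      res$torsions$chi1[[r]] <- ts
      res$states$rotamer[[r]] <- classify_rotamer(ts)
      emit(ts, write_series_csv, sprintf("chi1_torsion_rep%d.csv", r))
    }
    if ("rmsd" %in% analyses) {
      fit <- resolve_selection(fr, spec, "receptor_fit_atoms")
      lig <- which(fr$atoms$residue_name == spec$ligand_resname)
      rs <- ligand_rmsd_series(fr, fit, lig, reference_frame = reference_frame)
      res$rmsd[[r]] <- rs
      emit(rs, write_series_csv, sprintf("ligand_rmsd_rep%d.csv", r))
    }
    if (any(c("distances", "coupling") %in% analyses)) {
      term <- resolve_selection(fr, spec, "ligand_terminal_atoms")
      ring <- resolve_selection(fr, spec, "ring_atoms")
      ds <- min_distance_series(fr, term, ring_centroid(fr, ring),
                                label = "terminal_to_ring_centroid")
      res$distances[[r]] <- ds
      emit(ds, write_series_csv, sprintf("gate_distance_rep%d.csv", r))
    }
  }

  pool <- function(lst) dplyr::bind_rows(lapply(lst, as_tibble))
  res$summaries <- list()
  if (needs_chain) {
    pooled_chain <- new_state_tbl(pool(res$states$chain), "chain_mode")
    res$summaries$chain_mode <- list(
      per_replica = lapply(res$states$chain, summarize_states),
      pooled = summarize_states(pooled_chain)
    )
    res$histograms$chain <- circular_histogram(pool(res$torsions$chain), bins)
    res$heatmap <- state_heatmap(res$states$chain, downsample = downsample)
    emit(res$heatmap, write_heatmap_csv, "chain_mode_heatmap.csv")
    emit(res$histograms$chain, function(o, p)
      write.csv(as_tibble(o), p, row.names = FALSE), "chain_histogram.csv")
    emit(res$summaries$chain_mode$pooled, function(o, p)
      jsonlite::write_json(
        list(scheme = "chain_mode", n_frames = o$n_frames,
             n_transitions = o$n_transitions, per_state = tidy(o)),
        p, auto_unbox = TRUE, digits = NA, na = "null"),
      "chain_mode_summary.json")
  }
  if (needs_rot) {
    pooled_rot <- new_state_tbl(pool(res$states$rotamer), "rotamer")
    res$summaries$rotamer <- list(
      per_replica = lapply(res$states$rotamer, summarize_states),
      pooled = summarize_states(pooled_rot)
    )
    res$histograms$chi1 <- circular_histogram(pool(res$torsions$chi1), bins)
    emit(res$histograms$chi1, function(o, p)
      write.csv(as_tibble(o), p, row.names = FALSE), "chi1_histogram.csv")
    emit(res$summaries$rotamer$pooled, function(o, p)
      jsonlite::write_json(
        list(scheme = "rotamer", n_frames = o$n_frames,
             n_transitions = o$n_transitions, per_state = tidy(o)),
        p, auto_unbox = TRUE, digits = NA, na = "null"),
      "rotamer_summary.json")
  }
  if ("coupling" %in% analyses) {
    pooled_chain <- new_state_tbl(pool(res$states$chain), "chain_mode")
    pooled_rot <- new_state_tbl(pool(res$states$rotamer), "rotamer")
    pooled_dist <- pool(res$distances)
    res$coupling <- state_coupling(pooled_chain, pooled_rot,
                                   distances = pooled_dist,
                                   threshold = threshold)
    emit(res$coupling, write_coupling_json, "coupling_summary.json")
    emit(tidy(res$coupling), function(o, p)
      write.csv(o, p, row.names = FALSE), "contingency.csv")
  }
  if (!is.null(out_dir)) {
    log <- list(
      package_version = as.character(utils::packageVersion("ligmode")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config = config[setdiff(names(config), "selection")],
      config_hash = rlang::hash(config[setdiff(names(config), "selection")]),
      analyses = analyses, threshold = threshold, bins = bins,
      downsample = downsample, chi1_bw = chi1_bw,
      reference_frame = reference_frame
    )
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    res$files <- c(res$files, file.path(out_dir, "run_log.json"))
  }
  invisible(res)
}

#' Generate a synthetic dataset from a parameter file
#'
#' Thin wrapper around [write_synthetic_dataset()] accepting either a
#' [synthetic_params] object or a YAML/JSON file whose keys mirror the
#' [synthetic_params()] arguments. Rerunning with the same inputs
#' reproduces byte-identical files.
#'
#' @param params A [synthetic_params] object or a path to a YAML/JSON
#'   parameter file.
#' @param dir Output directory.
#' @return Invisibly, the [write_synthetic_dataset()] result.
#' @export
run_generate <- function(params, dir) {
  if (is.character(params) && length(params) == 1) {
    if (!file.exists(params)) {
      abort(paste0("parameter file not found: ", params),
            class = "ligmode_io_error")
    }
    x <- if (grepl("\\.json$", params, ignore.case = TRUE)) {
      jsonlite::fromJSON(params)
    } else {
      yaml::read_yaml(params)
    }
    if (!is.null(x$chain_transition)) {
      x$chain_transition <- matrix(unlist(x$chain_transition), 2, byrow = TRUE)
    }
    for (nm in c("chain_centers", "rotamer_centers", "distance_mean")) {
      if (!is.null(x[[nm]])) x[[nm]] <- unlist(x[[nm]])
    }
    params <- do.call(synthetic_params, x)
  }
  write_synthetic_dataset(params, dir)
}
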
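# state alphabets per scheme
chain_mode_levels <- c("MINUS_AC", "PLUS_AC")
rotamer_levels <- c("T", "GPLUS", "GMINUS")

new_state_tbl <- function(df, scheme) {
  structure(
    as_tibble(df),
    scheme = scheme,
    class = c("state_tbl", class(tibble()))
  )
}

#' Scheme of a state series
#' @param states A `state_tbl`.
#' @return `"chain_mode"` or `"rotamer"`.
#' @export
state_scheme <- function(states) attr(states, "scheme", exact = TRUE)

#' Classify a chain dihedral series into binding modes
#'
#' The alkyl-chain dihedral separates the two ligand poses by sign:
#' negative angles (minus-anticlinal regime, around -90 degrees) mark the
#' bent L-shape and positive angles (plus-anticlinal, around +90 degrees)
#' the extended I-shape. The boundary angle of exactly 0 is assigned
#' `PLUS_AC` so the rule is total.
#'
#' @param series A torsion tibble (columns `replica_id`, `frame`,
#'   `value` in degrees).
#' @return A `state_tbl` (scheme `"chain_mode"`) with the input columns
#'   plus `state` in `{MINUS_AC, PLUS_AC}`.
#' @export
classify_chain_mode <- function(series) {
  check_series(series)
  df <- as_tibble(series)
  df$state <- factor(ifelse(df$value < 0, "MINUS_AC", "PLUS_AC"),
                     levels = chain_mode_levels)
  new_state_tbl(df, "chain_mode")
}

#' Classify a chi1 series into side-chain rotamers
#'
#' Standard 120-degree staggered windows centred on the canonical
#' rotamers: `GPLUS` (gauche+, chi1 in \[-120, 0)), `GMINUS` (gauche-,
#' \[0, 120)) and `T` (trans/anti, the remaining third wrapping across
#' the +/-180 seam). The windows tile the circle exactly.
#'
#' @inheritParams classify_chain_mode
#' @return A `state_tbl` (scheme `"rotamer"`) with added `state` in
#'   `{T, GPLUS, GMINUS}`.
#' @export
classify_rotamer <- function(series) {
  check_series(series)
  df <- as_tibble(series)
  v <- wrap_angle(df$value)
  df$state <- factor(
    ifelse(v >= -120 & v < 0, "GPLUS",
           ifelse(v >= 0 & v < 120, "GMINUS", "T")),
    levels = rotamer_levels
  )
  new_state_tbl(df, "rotamer")
}

check_series <- function(series) {
  if (!is.data.frame(series) || !all(c("value", "frame") %in% names(series))) {
    abort("expected a series tibble with columns frame and value",
          class = "ligmode_invalid_input")
  }
  if (nrow(series) == 0) {
    abort("empty series", class = "ligmode_invalid_input")
  }
  invisible(series)
}

#' Summarise a discrete state series
#'
#' Reports per-state occupancy (label frequency), mean dwell time in
#' frames (mean length of consecutive runs), and — when the underlying
#' angles are available — the per-state circular mean and resultant
#' length; plus the total number of adjacent-frame transitions.
#'
#' @param states A `state_tbl` from [classify_chain_mode()] or
#'   [classify_rotamer()]. If it carries a `value` column those angles
#'   are used for the circular summaries.
#' @param angles Optional torsion tibble overriding the angles.
#' @return A `state_summary` object; see [tidy.state_summary()] and
#'   [glance.state_summary()] for tabular views.
#' @export
summarize_states <- function(states, angles = NULL) {
  if (!is.data.frame(states) || !"state" %in% names(states) ||
      nrow(states) == 0) {
    abort("states must be a nonempty state_tbl", class = "ligmode_invalid_input")
  }
  lab <- as.character(states$state)
  lev <- levels(states$state) %||% sort(unique(lab))
  ang <- if (!is.null(angles)) {
    if (nrow(angles) != nrow(states)) {
      abort("angles and states must have equal length",
            class = "ligmode_invalid_input")
    }
    angles$value
  } else if ("value" %in% names(states)) states$value else NULL
  n <- length(lab)
  runs <- rle(lab)
  occ <- as.numeric(table(factor(lab, levels = lev))) / n
  mean_dwell <- vapply(lev, function(s) {
    w <- runs$lengths[runs$values == s]
    if (length(w) == 0) NA_real_ else mean(w)
  }, numeric(1), USE.NAMES = FALSE)
  circ <- lapply(lev, function(s) {
    if (is.null(ang) || !any(lab == s)) {
      list(mean = NA_real_, resultant = NA_real_)
    } else {
      circular_mean(ang[lab == s])
    }
  })
  per_state <- tibble(
    state = lev,
    n_frames = as.integer(table(factor(lab, levels = lev))),
    occupancy = occ,
    mean_dwell = mean_dwell,
    circular_mean = vapply(circ, `[[`, numeric(1), "mean"),
    circular_resultant = vapply(circ, `[[`, numeric(1), "resultant")
  )
  structure(
    list(per_state = per_state,
         n_frames = n,
         n_transitions = length(runs$lengths) - 1L,
         scheme = state_scheme(states) %||% NA_character_,
         replica_id = if ("replica_id" %in% names(states))
           unique(states$replica_id) else NA_integer_),
    class = "state_summary"
  )
}

#' @export
print.state_summary <- function(x, ...) {
  cat(sprintf("<state_summary> scheme %s, %d frames, %d transition(s)\n",
              x$scheme, x$n_frames, x$n_transitions))
  print(x$per_state)
  invisible(x)
}

#' Tidy a state summary into a per-state tibble
#' @param x A `state_summary`.
#' @param ... Unused.
#' @return Tibble with one row per state.
#' @method tidy state_summary
#' @export
tidy.state_summary <- function(x, ...) x$per_state

#' One-row overview of a state summary
#' @param x A `state_summary`.
#' @param ... Unused.
#' @return One-row tibble: frames, transitions, number of visited states,
#'   and the modal state.
#' @method glance state_summary
#' @export
glance.state_summary <- function(x, ...) {
  ps <- x$per_state
  tibble(
    n_frames = x$n_frames,
    n_transitions = x$n_transitions,
    n_states_visited = sum(ps$n_frames > 0),
    modal_state = ps$state[which.max(ps$n_frames)],
    modal_occupancy = max(ps$occupancy)
  )
}

#' Circular histogram of a torsion series
#'
#' Counts over equal-width bins covering the full circle (-180, 180];
#' every finite angle falls in exactly one bin, so the counts sum to the
#' number of frames. The default 72 bins give 5-degree resolution.
#'
#' @param series Torsion tibble (or bare numeric vector of degrees).
#' @param n_bins Number of bins (>= 2), default 72.
#' @param normalized If `TRUE`, counts are divided by the total so the
#'   histogram is a probability mass function.
#' @return A tibble (`circular_histogram`) with columns `bin_lo`,
#'   `bin_hi`, `bin_mid` (degrees) and `count`.
#' @export
circular_histogram <- function(series, n_bins = 72, normalized = FALSE) {
  if (n_bins < 2) {
    abort("n_bins must be >= 2", class = "ligmode_config_error")
  }
  v <- if (is.data.frame(series)) series$value else series
  v <- wrap_angle(v)
  width <- 360 / n_bins
  edges <- seq(-180, 180, by = width)
  # values are in (-180, 180]; bin k covers (edges[k], edges[k+1]]
  idx <- ceiling((v + 180) / width)
  idx[idx < 1] <- 1L  # guard exact -180 after wrap (cannot occur, but safe)
  counts <- tabulate(idx, nbins = n_bins)
  out <- tibble(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1],
    bin_mid = (edges[-length(edges)] + edges[-1]) / 2,
    count = if (normalized) counts / length(v) else counts
  )
  structure(out, normalized = normalized,
            class = c("circular_histogram", class(tibble())))
}

#' Replica-by-time matrix of state codes
#'
#' Arranges one state series per replica into a matrix suitable for a
#' state heatmap. Downsampling replaces each non-overlapping window of
#' `downsample` frames by its modal label; within-window ties go to the
#' label that occurs earliest in the window.
#'
#' @param states_list A list of `state_tbl` objects (one per replica),
#'   or a single combined tibble with a `replica_id` column.
#' @param downsample Window size in frames (default 1 = no downsampling).
#' @return A character matrix (`state_heatmap`), rows in replica order,
#'   with `replica_id` row names.
#' @export
state_heatmap <- function(states_list, downsample = 1L) {
  if (is.data.frame(states_list)) {
    sc <- state_scheme(states_list)
    states_list <- split(as_tibble(states_list), states_list$replica_id)
    states_list <- lapply(states_list, new_state_tbl, scheme = sc)
  }
  if (length(states_list) < 1) {
    abort("need at least one replica", class = "ligmode_config_error")
  }
  schemes <- unique(vapply(states_list, function(s)
    state_scheme(s) %||% NA_character_, ""))
  if (length(schemes) > 1) {
    abort("replicas mix state schemes; refusing to aggregate",
          class = "ligmode_config_error")
  }
  rows <- lapply(states_list, function(s) {
    lab <- as.character(s$state)
    if (downsample <= 1) return(lab)
    starts <- seq(1, length(lab), by = downsample)
    vapply(starts, function(i) {
      w <- lab[i:min(i + downsample - 1, length(lab))]
      # modal label; ties broken by first occurrence within the window
      cnt <- table(factor(w, levels = unique(w)))
      names(cnt)[which.max(cnt)]
    }, "")
  })
  len <- vapply(rows, length, 1L)
  if (length(unique(len)) > 1) {
    abort("replicas have different lengths after downsampling",
          class = "ligmode_config_error")
  }
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(states_list, function(s)
    as.character(unique(s$replica_id)[1] %||% NA), "")
  structure(m, scheme = schemes, class = c("state_heatmap", "matrix"))
}

#' Write a state heatmap matrix to CSV
#'
#' Rows are replicas (labelled by `replica_id`), columns time windows.
#'
#' @param heatmap A `state_heatmap` matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_heatmap_csv <- function(heatmap, path) {
  df <- as.data.frame(unclass(heatmap))
  names(df) <- paste0("w", seq_len(ncol(df)))
  df <- cbind(replica_id = rownames(heatmap), df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
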
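#' Contingency table of two state series
#'
#' Frame-wise cross-tabulation of two simultaneous categorical series,
#' e.g. ligand chain mode against receptor rotamer state. Zero cells are
#' retained so downstream statistics see the full joint alphabet.
#'
#' @param a,b `state_tbl` objects (or any data frames with a `state`
#'   column) of equal length over the same frames.
#' @return An integer matrix, rows = states of `a`, columns = states of
#'   `b`; counts sum to the number of frames.
#' @export
contingency <- function(a, b) {
  for (s in list(a, b)) {
    if (!is.data.frame(s) || !"state" %in% names(s)) {
      abort("inputs must be state tibbles with a 'state' column",
            class = "ligmode_invalid_input")
    }
  }
  if (nrow(a) != nrow(b)) {
    abort(sprintf("state series lengths differ: %d vs %d", nrow(a), nrow(b)),
          class = "ligmode_invalid_input")
  }
  if (nrow(a) == 0) {
    abort("empty state series", class = "ligmode_invalid_input")
  }
  fa <- if (is.factor(a$state)) a$state else factor(a$state)
  fb <- if (is.factor(b$state)) b$state else factor(b$state)
  m <- table(fa, fb)
  m <- matrix(as.integer(m), nrow = nlevels(fa),
              dimnames = list(levels(fa), levels(fb)))
  m
}

#' Association statistics of a contingency table
#'
#' The minimal standard trio for categorical association:
#'
#' * odds ratio (when the table, after dropping never-visited states
#'   with zero marginals, is 2 x 2), with the Haldane-Anscombe +0.5
#'   correction applied to every cell whenever any cell is zero — MD
#'   trajectories commonly never visit one joint state;
#' * Cramer's V from the chi-squared statistic (no continuity
#'   correction), in \[0, 1\];
#' * mutual information in bits from the empirical joint distribution.
#'
#' @param table Count matrix (k x m; 2 x 2 for the odds ratio).
#' @return List with `odds_ratio` (`NA` for non-2x2 tables),
#'   `cramers_v` and `mutual_information`.
#' @export
association_stats <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0) || sum(m) == 0) {
    abort("contingency table must be nonnegative with a positive total",
          class = "ligmode_invalid_input")
  }
  n <- sum(m)
  # rows/columns with zero marginals (never-visited states) carry no
  # information; drop them before computing the statistics
  nz <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  odds_ratio <- NA_real_
  if (all(dim(nz) == c(2, 2))) {
    mm <- if (any(nz == 0)) nz + 0.5 else nz
    odds_ratio <- (mm[1, 1] * mm[2, 2]) / (mm[1, 2] * mm[2, 1])
  }
  cramers_v <- 0
  if (nrow(nz) > 1 && ncol(nz) > 1) {
    expected <- outer(rowSums(nz), colSums(nz)) / n
    chi2 <- sum((nz - expected)^2 / expected)
    cramers_v <- sqrt(chi2 / (n * min(nrow(nz) - 1, ncol(nz) - 1)))
    cramers_v <- min(1, cramers_v)
  }
  # mutual information (bits) over nonzero cells
  p <- nz / n
  pr <- rowSums(p)
  pc <- colSums(p)
  mi <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) {
        mi <- mi + p[i, j] * log2(p[i, j] / (pr[i] * pc[j]))
      }
    }
  }
  list(odds_ratio = odds_ratio, cramers_v = cramers_v,
       mutual_information = max(0, mi))
}

#' Chain-mode / rotamer coupling summary
#'
#' Cross-tabulates the ligand chain mode against the residue rotamer
#' state and attaches the association statistics; optionally also the
#' distance gate when a distance series is supplied. This is the
#' package's quantitative form of the claim that the extended I-shape
#' pose goes together with the gauche+ rotamer.
#'
#' @param chain Chain-mode `state_tbl`.
#' @param rotamer Rotamer `state_tbl` over the same frames.
#' @param distances Optional distance tibble for [distance_gate()].
#' @param threshold Gate threshold in Angstrom (default 5).
#' @return A `coupling_summary` object with elements `table`,
#'   `odds_ratio`, `cramers_v`, `mutual_information`, `n_frames` and
#'   (when distances are given) `gate`.
#' @export
state_coupling <- function(chain, rotamer, distances = NULL, threshold = 5) {
  tab <- contingency(chain, rotamer)
  stats <- association_stats(tab)
  gate <- if (!is.null(distances)) {
    distance_gate(distances, chain, threshold = threshold)
  } else NULL
  structure(
    c(list(table = tab, n_frames = sum(tab), gate = gate,
           threshold = if (is.null(gate)) NA_real_ else threshold),
      stats),
    class = "coupling_summary"
  )
}

#' @export
print.coupling_summary <- function(x, ...) {
  cat(sprintf("<coupling_summary> %d frames\n", x$n_frames))
  print(x$table)
  cat(sprintf("odds ratio %.3g | Cramer's V %.3f | MI %.3f bits\n",
              x$odds_ratio, x$cramers_v, x$mutual_information))
  if (!is.null(x$gate)) {
    cat(sprintf("distance gate at %g Angstrom:\n", x$threshold))
    print(x$gate)
  }
  invisible(x)
}

#' Tidy a coupling summary into one row per joint state
#' @param x A `coupling_summary`.
#' @param ... Unused.
#' @return Tibble with columns `chain_state`, `rotamer_state`, `n`,
#'   `proportion`.
#' @method tidy coupling_summary
#' @export
tidy.coupling_summary <- function(x, ...) {
  df <- as.data.frame(as.table(x$table), stringsAsFactors = FALSE)
  names(df) <- c("chain_state", "rotamer_state", "n")
  df$n <- as.integer(df$n)
  df$proportion <- df$n / sum(df$n)
  as_tibble(df)
}

#' One-row overview of a coupling summary
#' @param x A `coupling_summary`.
#' @param ... Unused.
#' @return One-row tibble of the association statistics.
#' @method glance coupling_summary
#' @export
glance.coupling_summary <- function(x, ...) {
  tibble(n_frames = x$n_frames, odds_ratio = x$odds_ratio,
         cramers_v = x$cramers_v, mutual_information = x$mutual_information)
}

#' Serialise a coupling summary to JSON
#' @param x A `coupling_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coupling_json <- function(x, path) {
  stopifnot(inherits(x, "coupling_summary"))
  out <- list(
    n_frames = x$n_frames,
    table = list(
      rows = rownames(x$table), cols = colnames(x$table),
      counts = lapply(seq_len(nrow(x$table)), function(i)
        as.integer(x$table[i, ]))
    ),
    odds_ratio = x$odds_ratio,
    cramers_v = x$cramers_v,
    mutual_information = x$mutual_information
  )
  if (!is.null(x$gate)) {
    out$threshold <- x$threshold
    out$gate <- x$gate
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Distance gating by chain state
#'
#' For each chain-mode state, the fraction of frames whose gate distance
#' (e.g. terminal methyl carbon to aromatic-ring centroid) falls below
#' the threshold, together with the per-state mean/min/max. A state that
#' is never visited is reported with `NA` statistics, not zeros.
#'
#' @param distances Distance tibble (column `value`, Angstrom).
#' @param chain Chain-mode `state_tbl` over the same frames.
#' @param threshold Gate threshold in Angstrom (> 0), default 5 — the
#'   contact criterion separating the two binding modes.
#' @return Tibble with columns `state`, `n`, `below_threshold_fraction`,
#'   `mean`, `min`, `max`.
#' @export
distance_gate <- function(distances, chain, threshold = 5) {
  if (threshold <= 0) {
    abort("threshold must be positive", class = "ligmode_config_error")
  }
  if (nrow(distances) != nrow(chain)) {
    abort("distance and state series must have equal length",
          class = "ligmode_invalid_input")
  }
  lev <- levels(chain$state) %||% unique(as.character(chain$state))
  d <- distances$value
  s <- as.character(chain$state)
  purrr::map_dfr(lev, function(st) {
    di <- d[s == st]
    if (length(di) == 0) {
      tibble(state = st, n = 0L, below_threshold_fraction = NA_real_,
             mean = NA_real_, min = NA_real_, max = NA_real_)
    } else {
      tibble(state = st, n = length(di),
             below_threshold_fraction = mean(di < threshold),
             mean = mean(di), min = min(di), max = max(di))
    }
  })
}
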
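#' Configuration for CHO formula assignment
#'
#' Bounds and tolerances for exhaustive CHO formula enumeration. Defaults
#' cover the low-mass (< 800 Da) polyphenol space: C <= 40, H <= 80,
#' O <= 40, H/C in \[0.3, 2.2\], O/C <= 1, integer DBE >= 0, 0.5 ppm.
#'
#' @param tol_ppm Relative mass tolerance in ppm (> 0).
#' @param c_max,h_max,o_max Element upper bounds.
#' @param hc_range Allowed H/C interval.
#' @param oc_max Allowed O/C maximum.
#' @param require_integer_dbe Require integer DBE (even hydrogen count for a
#'   CHO neutral molecule).
#' @return A list of class `assignment_config`.
#' @export
assignment_config <- function(tol_ppm = 0.5, c_max = 40L, h_max = 80L,
                              o_max = 40L, hc_range = base::c(0.3, 2.2),
                              oc_max = 1, require_integer_dbe = TRUE) {
  stopifnot(tol_ppm > 0, c_max >= 1, h_max >= 0, o_max >= 0,
            length(hc_range) == 2L, hc_range[1] >= 0, hc_range[2] <= 3)
  structure(
    list(tol_ppm = tol_ppm, c_max = as.integer(c_max),
         h_max = as.integer(h_max), o_max = as.integer(o_max),
         hc_range = hc_range, oc_max = oc_max,
         require_integer_dbe = isTRUE(require_integer_dbe)),
    class = "assignment_config"
  )
}

#' Enumerate CHO formula candidates for a neutral mass
#'
#' Scans the full (C, O) grid within bounds; for each pair the hydrogen
#' count is pinned by the mass (the tolerance window is far narrower than
#' one hydrogen mass). Candidates must satisfy the H/C window, the O/C
#' maximum and DBE >= 0 (integer when required). The result is sorted by
#' absolute mass error, ties broken by fewer oxygens then fewer carbons.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (> 0).
#' @param config An [assignment_config()].
#' @return Data frame with formula columns `c`, `h`, `o`, `d`, `br`, plus
#'   `formula`, `mass`, `error_ppm`; zero rows when nothing matches.
#' @export
#' @examples
#' enumerate_candidates(122.036779)  # C7H6O2
enumerate_candidates <- function(neutral_mass, config = assignment_config()) {
  stopifnot(length(neutral_mass) == 1L, neutral_mass > 0)
  am <- atomic_masses()
  grid_c <- seq_len(config$c_max)
  grid_o <- 0:config$o_max
  cc <- rep(grid_c, times = length(grid_o))
  oo <- rep(grid_o, each = length(grid_c))
  ok <- oo / cc <= config$oc_max
  cc <- cc[ok]
  oo <- oo[ok]
  h_exact <- (neutral_mass - am[["C"]] * cc - am[["O"]] * oo) / am[["H"]]
  cand <- function(hh) {
    keep <- hh >= 0L & hh <= config$h_max &
      hh / cc >= config$hc_range[1] & hh / cc <= config$hc_range[2] &
      hh <= 2L * cc + 2L
    if (config$require_integer_dbe) keep <- keep & hh %% 2L == 0L
    keep <- keep & (cc - hh / 2 + 1) >= 0
    mass <- am[["C"]] * cc + am[["H"]] * hh + am[["O"]] * oo
    err <- (mass - neutral_mass) / neutral_mass * 1e6
    keep <- keep & abs(err) <= config$tol_ppm
    data.frame(c = cc[keep], h = hh[keep], o = oo[keep],
               mass = mass[keep], error_ppm = err[keep])
  }
  out <- rbind(cand(as.integer(floor(h_exact))),
               cand(as.integer(ceiling(h_exact))))
  out <- out[!duplicated(out[, base::c("c", "h", "o")]), , drop = FALSE]
  out <- out[order(abs(out$error_ppm), out$o, out$c), , drop = FALSE]
  rownames(out) <- NULL
  out$d <- rep(0L, nrow(out))
  out$br <- rep(0L, nrow(out))
  out$formula <- if (nrow(out)) formula_label(out) else character()
  out[, base::c("c", "h", "o", "d", "br", "formula", "mass", "error_ppm")]
}

#' Assign CHO formulae to the peaks of a negative-mode spectrum
#'
#' For each peak the neutral mass is computed as m/z plus the proton mass
#' and the best candidate within tolerance retained (smallest absolute
#' error; ties by fewer oxygens then fewer carbons). Peaks with two or more
#' candidates within tolerance are kept but flagged `ambiguous`; peaks with
#' none are omitted and counted in the summary attribute.
#'
#' @param spectrum A negative-mode `mass_spectrum`.
#' @param config An [assignment_config()].
#' @return A data frame of class `formula_assignments` with columns
#'   `peak_idx`, `mz`, `intensity`, `c`, `h`, `o`, `d`, `br`, `formula`,
#'   `error_ppm`, `n_candidates`, `ambiguous`, and an attribute `summary`
#'   (list with `n_peaks`, `n_assigned`, `n_unassigned`, `n_ambiguous`).
#' @export
assign_formulas <- function(spectrum, config = assignment_config()) {
  if (!identical(spectrum$polarity, "negative")) {
    stop("formula assignment requires a negative-mode spectrum")
  }
  pk <- spectrum$peaks
  res <- vector("list", nrow(pk))
  for (i in seq_len(nrow(pk))) {
    cand <- enumerate_candidates(neutral_mass_from_mz(pk$mz[i]), config)
    if (nrow(cand)) {
      res[[i]] <- data.frame(
        peak_idx = i, mz = pk$mz[i], intensity = pk$intensity[i],
        cand[1L, base::c("c", "h", "o", "d", "br", "formula", "error_ppm")],
        n_candidates = nrow(cand), ambiguous = nrow(cand) > 1L
      )
    }
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(
      peak_idx = integer(), mz = numeric(), intensity = numeric(),
      c = integer(), h = integer(), o = integer(), d = integer(),
      br = integer(), formula = character(), error_ppm = numeric(),
      n_candidates = integer(), ambiguous = logical()
    )
  }
  rownames(out) <- NULL
  attr(out, "summary") <- list(
    n_peaks = nrow(pk),
    n_assigned = nrow(out),
    n_unassigned = nrow(pk) - nrow(out),
    n_ambiguous = sum(out$ambiguous)
  )
  class(out) <- base::c("formula_assignments", "data.frame")
  out
}

#' Export an assignment table as CSV
#'
#' Adds the derived descriptors (DBE, O/C, H/C, AI, compound class) to the
#' assignment table and writes it to disk.
#'
#' @param assignments A `formula_assignments` table.
#' @param path Output CSV path.
#' @param thresholds Compound-class thresholds, see [class_thresholds()].
#' @return The augmented data frame, invisibly.
#' @export
write_assignments <- function(assignments, path,
                              thresholds = class_thresholds()) {
  df <- as.data.frame(assignments)
  if (nrow(df)) {
    df$dbe <- dbe(df)
    df$oc <- oc_ratio(df)
    df$hc <- hc_ratio(df)
    df$ai <- aromaticity_index(df)
    df$class <- compound_class(df, thresholds)
  } else {
    df$dbe <- numeric()
    df$oc <- numeric()
    df$hc <- numeric()
    df$ai <- numeric()
    df$class <- character()
  }
  cols <- base::c("mz", "intensity", "formula", "error_ppm", "dbe", "oc",
                  "hc", "ai", "class")
  utils::write.csv(df[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
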
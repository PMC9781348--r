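#' Detect labeling peak series in a spectrum
#'
#' Extracts peak series separated by integer multiples of a labeling
#' reaction's per-event mass shift. For every candidate base peak the
#' maximal consecutive chain of members at `base + k * delta` (k = 1, 2,
#' ...) is built: at each k the peak closest to the ideal position is taken,
#' provided it lies within `tol_mz` of that position (positions are measured
#' from the base, so tolerance does not accumulate along the chain; exact
#' distance ties break toward the lower m/z peak). The chain stops at the
#' first missing k. A chain is reported once, under its lowest-m/z base: a
#' peak that could itself be the k = 1 member of a lower base (a peak lies
#' within `tol_mz` of its m/z minus delta) is not reported as a base. Chains
#' without any labeled member (`max_k` = 0) are suppressed.
#'
#' @param spectrum A `mass_spectrum`.
#' @param reaction Reaction name, see [reactions()].
#' @param tol_mz Absolute m/z tolerance between a member and its ideal chain
#'   position, in Th. The default 0.0003 reflects sub-ppm FTICR mass
#'   accuracy between peaks of a series.
#' @param k_max Largest event count searched (default 12, an upper bound on
#'   exchangeable-hydrogen counts of < 800 Da polyphenols).
#' @return A data frame of class `label_series` with one row per series:
#'   `series_id`, `reaction`, `base_idx`, `base_mz`, `base_intensity`,
#'   `max_k`, and list columns `member_k` (event counts, starting at 0),
#'   `member_idx`, `member_mz`.
#' @export
#' @examples
#' sp <- mass_spectrum(c(121.0295, 122.0358, 123.0421), c(3, 2, 1))
#' detect_series(sp, "HD_EXCHANGE")
detect_series <- function(spectrum, reaction, tol_mz = 0.0003, k_max = 12L) {
  stopifnot(tol_mz > 0, k_max >= 1L)
  delta <- reaction_mass_shift(reaction)
  mz <- spectrum$peaks$mz
  n <- length(mz)
  empty <- data.frame(
    series_id = character(), reaction = character(), base_idx = integer(),
    base_mz = numeric(), base_intensity = numeric(), max_k = integer()
  )
  empty$member_k <- list()
  empty$member_idx <- list()
  empty$member_mz <- list()
  class(empty) <- base::c("label_series", "data.frame")
  if (n == 0L) return(empty)
  # members at k = 1..k_max for every peak as candidate base
  memb <- matrix(NA_integer_, nrow = n, ncol = k_max)
  for (k in seq_len(k_max)) {
    memb[, k] <- nearest_peak_idx(mz, mz + k * delta, tol_mz)
  }
  # consecutive-prefix length
  present <- !is.na(memb)
  if (k_max > 1L) {
    for (k in 2:k_max) present[, k] <- present[, k] & present[, k - 1L]
  }
  max_k <- rowSums(present)
  # suppression: peak reachable as a k = 1 member of some lower chain
  has_pred <- !is.na(nearest_peak_idx(mz, mz - delta, tol_mz))
  bases <- which(max_k >= 1L & !has_pred)
  if (!length(bases)) return(empty)
  out <- data.frame(
    series_id = paste0(reaction, "@", sprintf("%.5f", mz[bases])),
    reaction = reaction,
    base_idx = bases,
    base_mz = mz[bases],
    base_intensity = spectrum$peaks$intensity[bases],
    max_k = as.integer(max_k[bases])
  )
  out$member_k <- lapply(seq_along(bases), function(j) 0:max_k[bases[j]])
  out$member_idx <- lapply(seq_along(bases), function(j) {
    b <- bases[j]
    base::c(b, memb[b, seq_len(max_k[b])])
  })
  out$member_mz <- lapply(out$member_idx, function(i) mz[i])
  rownames(out) <- NULL
  class(out) <- base::c("label_series", "data.frame")
  out
}

#' Chemical feasibility rules for labeling series
#'
#' Default per-reaction upper bounds on the number of labeling events a base
#' formula can support, given its element counts:
#' \describe{
#'   \item{HD_EXCHANGE}{at most `h` events (every hydrogen could exchange).}
#'   \item{DEUTEROMETHYLATION}{at most `floor(o/2)` events (each carboxyl
#'     consumes two oxygens).}
#'   \item{REDUCTION}{at most `o - n_dm` events, where `n_dm` is the number
#'     of deuteromethylation events when known (carbonyl oxygens are those
#'     not already in carboxyls).}
#'   \item{BROMINATION}{at most `max(0, round(dbe) - 3)` events (an aromatic
#'     ring requires DBE >= 4); interpreted downstream as presence/absence
#'     evidence only.}
#' }
#'
#' @return Named list of functions `(formula_row, n_dm) -> integer` giving
#'   the maximum feasible event count.
#' @export
series_rules <- function() {
  list(
    HD_EXCHANGE = function(f, n_dm = 0L) f$h,
    DEUTEROMETHYLATION = function(f, n_dm = 0L) f$o %/% 2L,
    REDUCTION = function(f, n_dm = 0L) max(0L, f$o - n_dm),
    BROMINATION = function(f, n_dm = 0L) max(0L, round(dbe(f)) - 3L)
  )
}

#' Filter detected series with chemistry-based rules
#'
#' Retains only series whose base peak carries a valid unlabeled formula
#' assignment (`d` = 0) and whose observed `max_k` is chemically feasible
#' for that formula under the reaction (see [series_rules()]). Rejected
#' series are kept in the `rejections` attribute together with the violated
#' rule.
#'
#' @param series A `label_series` table from [detect_series()].
#' @param assignments A `formula_assignments` table for the same spectrum
#'   (base peaks are matched by peak index when available, else by m/z).
#' @param rules Named list of feasibility functions, see [series_rules()].
#' @param n_dm Known deuteromethylation event counts per base formula, used
#'   by the REDUCTION rule (a single integer applied to all, default 0).
#' @return The retained subset, with columns `formula`, `c`, `h`, `o`
#'   appended; attribute `rejections` is a data frame with `series_id` and
#'   `rule`.
#' @export
filter_series <- function(series, assignments, rules = series_rules(),
                          n_dm = 0L) {
  if (!nrow(series)) {
    attr(series, "rejections") <- data.frame(series_id = character(),
                                             rule = character())
    return(series)
  }
  asg <- as.data.frame(assignments)
  hit <- match(series$base_idx, asg$peak_idx)
  keep <- logical(nrow(series))
  rule_broken <- character(nrow(series))
  feas <- vapply(seq_len(nrow(series)), function(i) {
    j <- hit[i]
    if (is.na(j)) return(NA_integer_)
    if (asg$d[j] != 0L) return(-1L)
    fn <- rules[[series$reaction[i]]]
    if (is.null(fn)) stop("no feasibility rule for ", series$reaction[i])
    as.integer(fn(asg[j, , drop = FALSE], n_dm))
  }, integer(1))
  keep <- !is.na(feas) & feas >= 0L & series$max_k <= feas
  rule_broken[is.na(feas)] <- "no_formula_assignment"
  rule_broken[!is.na(feas) & feas == -1L] <- "base_formula_labeled"
  rule_broken[!is.na(feas) & feas >= 0L & series$max_k > feas] <-
    "max_k_infeasible"
  out <- series[keep, , drop = FALSE]
  j <- hit[keep]
  out$formula <- asg$formula[j]
  out$c <- asg$c[j]
  out$h <- asg$h[j]
  out$o <- asg$o[j]
  rownames(out) <- NULL
  attr(out, "rejections") <- data.frame(
    series_id = series$series_id[!keep],
    rule = rule_broken[!keep]
  )
  class(out) <- base::c("label_series", "data.frame")
  out
}

#' Fold per-reaction series into a functional-group descriptor
#'
#' Series lengths map onto structural descriptors: deuteromethylation
#' events count carboxyl groups, reduction events count carbonyl groups, a
#' bromination series marks aromaticity, H/D-exchange events count
#' exchangeable hydrogens. A reaction absent from `experiments_run` yields
#' an unknown (`NA`) descriptor; a reaction that was run but produced no
#' series yields 0 (or `FALSE` for bromination).
#'
#' @param formula A single-row `chem_formula` (the unlabeled base).
#' @param series_by_reaction Named list mapping reaction names to a
#'   `label_series` row (or a table whose relevant row is the one matching
#'   the base formula); reactions without a series may be absent or NULL.
#' @param experiments_run Character vector of reactions actually performed.
#' @return A one-row data frame: `formula`, `n_cooh`, `n_carbonyl`,
#'   `is_aromatic`, `n_exchangeable`, `complete` (all three structural
#'   descriptors known).
#' @export
descriptors_from_series <- function(formula, series_by_reaction = list(),
                                    experiments_run = names(series_by_reaction)) {
  formula <- as_chem_formula(formula)
  stopifnot(nrow(formula) == 1L)
  lab <- formula_label(formula)
  grab <- function(reaction) {
    s <- series_by_reaction[[reaction]]
    if (is.null(s) || !nrow(s)) {
      if (reaction %in% experiments_run) return(0L)
      return(NA_integer_)
    }
    if (!is.null(s$formula) && !all(s$formula == lab)) {
      stop("series base formula mismatch for ", lab, " (", reaction, ")")
    }
    max(s$max_k)
  }
  n_cooh <- grab("DEUTEROMETHYLATION")
  n_carbonyl <- grab("REDUCTION")
  n_br <- grab("BROMINATION")
  n_hd <- grab("HD_EXCHANGE")
  data.frame(
    formula = lab,
    n_cooh = n_cooh,
    n_carbonyl = n_carbonyl,
    is_aromatic = if (is.na(n_br)) NA else n_br >= 1L,
    n_exchangeable = n_hd,
    complete = !is.na(n_cooh) && !is.na(n_carbonyl) && !is.na(n_br)
  )
}

#' Export a series table as CSV
#'
#' @param series A `label_series` table (filtered tables include formulae).
#' @param path Output CSV path.
#' @return The flattened data frame, invisibly.
#' @export
write_series <- function(series, path) {
  df <- as.data.frame(series)
  df$member_mzs <- vapply(
    series$member_mz, function(m) paste(sprintf("%.6f", m), collapse = ";"),
    character(1)
  )
  cols <- base::c("base_mz",
                  if (!is.null(df$formula)) "formula",
                  "reaction", "max_k", "member_mzs")
  utils::write.csv(df[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(df[, cols])
}
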
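#' Build a solvent-fraction molecular profile
#'
#' A fraction profile maps assigned molecular formulae to their summed
#' intensities within one solvent fraction's spectrum.
#'
#' @param fraction_id Solvent-composition label, e.g. `"100% CH3OH"`.
#' @param formulas A `chem_formula` table (or formula strings).
#' @param intensity Non-negative intensities, one per formula; duplicate
#'   formulae are summed.
#' @return A data frame of class `fraction_profile` with formula columns,
#'   `formula` labels and `intensity`; attributes `fraction_id` and
#'   `totals` (list with `intensity`, `n_formulas`).
#' @export
fraction_profile <- function(fraction_id, formulas, intensity) {
  f <- as_chem_formula(formulas)
  if (length(intensity) != nrow(f)) {
    stop("one intensity per formula required")
  }
  if (any(intensity < 0)) stop("intensities must be non-negative")
  lab <- formula_label(f)
  agg <- rowsum(intensity, lab)
  keep <- !duplicated(lab)
  df <- as.data.frame(f)[keep, , drop = FALSE]
  df$formula <- lab[keep]
  df$intensity <- agg[match(df$formula, rownames(agg)), 1L]
  df <- df[order(df$formula), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            fraction_id = fraction_id,
            totals = list(intensity = sum(df$intensity),
                          n_formulas = nrow(df)),
            class = base::c("fraction_profile", "data.frame"))
}

#' @export
print.fraction_profile <- function(x, ...) {
  cat("<fraction_profile> ", attr(x, "fraction_id"), ": ", nrow(x),
      " formulae, total intensity ",
      format(attr(x, "totals")$intensity, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Profile a fraction from a spectrum's formula assignments
#'
#' @param assignments A `formula_assignments` table for the fraction's
#'   spectrum.
#' @param fraction_id Solvent-composition label.
#' @return A [fraction_profile()].
#' @export
profile_from_assignments <- function(assignments, fraction_id) {
  df <- as.data.frame(assignments)
  fraction_profile(fraction_id,
                   chem_formula(df$c, df$h, df$o, df$d, df$br),
                   df$intensity)
}

#' Number-averaged molecular metric of a fraction
#'
#' The unweighted mean of a formula-level metric over all assigned formulae
#' (the conventional "(metric)n" of ultrahigh-resolution MS), or the
#' intensity-weighted mean.
#'
#' @param profile A `fraction_profile`.
#' @param metric One of `"oc"`, `"hc"`, `"ai"`, `"mass"`.
#' @param weighting `"none"` (default, the number average) or
#'   `"intensity"`.
#' @return A single numeric value.
#' @export
number_average <- function(profile, metric = base::c("oc", "hc", "ai", "mass"),
                           weighting = base::c("none", "intensity")) {
  metric <- match.arg(metric)
  weighting <- match.arg(weighting)
  if (!nrow(profile)) stop("empty fraction profile")
  vals <- switch(metric,
    oc = oc_ratio(profile),
    hc = hc_ratio(profile),
    ai = aromaticity_index(profile),
    mass = monoisotopic_mass(profile)
  )
  if (weighting == "none") {
    mean(vals)
  } else {
    stats::weighted.mean(vals, profile$intensity)
  }
}

#' Compound-class distribution of a fraction
#'
#' Tallies [compound_class()] over the profile's formulae. Classes listed
#' in `exclude` (by default the lipid-like class, unlikely indigenous to a
#' polyphenolic material) are removed before share computation, so shares
#' over the retained classes sum to 1.
#'
#' @param profile A `fraction_profile`.
#' @param exclude Character vector of class labels to drop.
#' @param thresholds Class thresholds, see [class_thresholds()].
#' @return Data frame `class`, `count`, `count_share`, `intensity_share`
#'   (zero rows for an empty or fully excluded profile).
#' @export
class_distribution <- function(profile, exclude = "LIPID_LIKE",
                               thresholds = class_thresholds()) {
  if (!nrow(profile)) {
    return(data.frame(class = character(), count = integer(),
                      count_share = numeric(), intensity_share = numeric()))
  }
  cls <- compound_class(profile, thresholds)
  keep <- !(cls %in% exclude)
  cls <- cls[keep]
  int <- profile$intensity[keep]
  if (!length(cls)) {
    return(data.frame(class = character(), count = integer(),
                      count_share = numeric(), intensity_share = numeric()))
  }
  lev <- intersect(compound_classes(), unique(cls))
  count <- vapply(lev, function(l) sum(cls == l), integer(1))
  intsum <- vapply(lev, function(l) sum(int[cls == l]), numeric(1))
  data.frame(
    class = lev,
    count = count,
    count_share = count / sum(count),
    intensity_share = if (sum(intsum) > 0) intsum / sum(intsum)
                      else rep(NA_real_, length(lev)),
    row.names = NULL
  )
}

#' Intensity share of target components in a fraction
#'
#' The summed intensity of the profile's formulae that belong to the target
#' set, divided by the profile's total intensity — the contribution of the
#' targeted components to the fraction's spectrum.
#'
#' @param profile A non-empty `fraction_profile`.
#' @param targets A `chem_formula` table or character vector of formula
#'   labels (e.g. the liver-detected component list).
#' @return A share in \[0, 1\].
#' @export
enrichment_score <- function(profile, targets) {
  if (!nrow(profile)) stop("empty fraction profile")
  if (!is.character(targets)) targets <- formula_label(targets)
  tot <- sum(profile$intensity)
  if (tot <= 0) return(0)
  sum(profile$intensity[profile$formula %in% targets]) / tot
}

#' Rank fractions by target enrichment
#'
#' Stable sort of fraction profiles by decreasing [enrichment_score()];
#' ties preserve input order.
#'
#' @param profiles List of `fraction_profile` objects (at least one).
#' @param targets Target formulae, see [enrichment_score()].
#' @return The input list reordered, with a `scores` attribute (named
#'   numeric vector in the returned order).
#' @export
rank_fractions <- function(profiles, targets) {
  stopifnot(length(profiles) >= 1L)
  scores <- vapply(profiles, enrichment_score, numeric(1), targets = targets)
  ord <- order(-scores)  # order() is a stable sort
  out <- profiles[ord]
  attr(out, "scores") <- stats::setNames(
    scores[ord],
    vapply(out, attr, character(1), which = "fraction_id")
  )
  out
}

#' Export a fraction's van Krevelen table (and optional plot)
#'
#' Writes one row per formula with O/C (x), H/C (y), intensity and
#' compound class; optionally renders a scatter PNG colored by class.
#'
#' @param profile A `fraction_profile`.
#' @param path Output CSV path.
#' @param plot_path Optional PNG path for a van Krevelen scatter.
#' @param thresholds Class thresholds.
#' @return The exported data frame, invisibly.
#' @export
van_krevelen_export <- function(profile, path, plot_path = NULL,
                                thresholds = class_thresholds()) {
  df <- data.frame(
    formula = profile$formula,
    oc = oc_ratio(profile),
    hc = hc_ratio(profile),
    intensity = profile$intensity,
    class = if (nrow(profile)) compound_class(profile, thresholds)
            else character()
  )
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write van Krevelen table to ", path, ": ",
                        conditionMessage(ok))
  if (!is.null(plot_path)) {
    grDevices::png(plot_path, width = 900, height = 700, res = 120)
    on.exit(grDevices::dev.off(), add = TRUE)
    pal <- stats::setNames(
      base::c("#b2182b", "#ef8a62", "#999999", "#67a9cf", "#2166ac"),
      compound_classes()
    )
    plot(df$oc, df$hc, col = pal[df$class], pch = 16,
         cex = 0.6, xlab = "O/C", ylab = "H/C",
         main = attr(profile, "fraction_id"))
    graphics::legend("topright", legend = names(pal), col = pal, pch = 16,
                     cex = 0.7)
  }
  invisible(df)
}
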
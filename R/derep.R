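#' Bundle tissue-extract and reference spectra into a sample set
#'
#' @param control List of `mass_spectrum` objects from untreated-tissue
#'   extracts (replicates).
#' @param labeled_admin Named list keyed by administration route
#'   (`"parenteral"`, `"oral"`); each element a list of spectra recorded
#'   after administration of the D-labeled material.
#' @param labeled_ref List of spectra of the D-labeled material itself.
#' @param parent_ref Optional list of spectra of the unlabeled material.
#' @return An object of class `sample_set`.
#' @export
sample_set <- function(control, labeled_admin, labeled_ref,
                       parent_ref = NULL) {
  as_list <- function(x) if (inherits(x, "mass_spectrum")) list(x) else x
  control <- as_list(control)
  labeled_ref <- as_list(labeled_ref)
  if (!length(control)) stop("sample set requires control spectra")
  if (!length(labeled_ref)) stop("sample set requires labeled_ref spectra")
  if (!is.list(labeled_admin) || is.null(names(labeled_admin))) {
    stop("labeled_admin must be a named list keyed by route")
  }
  bad <- setdiff(names(labeled_admin), base::c("parenteral", "oral"))
  if (length(bad)) stop("unknown route(s): ", paste(bad, collapse = ", "))
  labeled_admin <- lapply(labeled_admin, as_list)
  if (!is.null(parent_ref)) parent_ref <- as_list(parent_ref)
  structure(
    list(control = control, labeled_admin = labeled_admin,
         labeled_ref = labeled_ref, parent_ref = parent_ref),
    class = "sample_set"
  )
}

#' @export
print.sample_set <- function(x, ...) {
  cat("<sample_set> control:", length(x$control),
      "| labeled_admin:",
      paste(names(x$labeled_admin),
            vapply(x$labeled_admin, length, integer(1)),
            sep = "=", collapse = " "),
      "| labeled_ref:", length(x$labeled_ref),
      "| parent_ref:", length(x$parent_ref), "\n")
  invisible(x)
}

#' Configuration of the exogenous-component pipeline
#'
#' @param tol_mz Series-detection tolerance in Th.
#' @param k_max Largest event count searched.
#' @param assignment An [assignment_config()] for base-peak formula
#'   assignment.
#' @param min_support Minimum number of replicate spectra (within the best
#'   route) a component must be detected in to survive [final_filter()].
#' @param require_labeled_ref Require the component's series base to appear
#'   among the labeled reference material's series.
#' @param hc_range,oc_range Formula windows components must fall in.
#' @return A list of class `derep_config`.
#' @export
derep_config <- function(tol_mz = 0.0003, k_max = 12L,
                         assignment = assignment_config(),
                         min_support = 2L, require_labeled_ref = TRUE,
                         hc_range = base::c(0.3, 2.2),
                         oc_range = base::c(0, 1)) {
  structure(
    list(tol_mz = tol_mz, k_max = as.integer(k_max), assignment = assignment,
         min_support = as.integer(min_support),
         require_labeled_ref = isTRUE(require_labeled_ref),
         hc_range = hc_range, oc_range = oc_range),
    class = "derep_config"
  )
}

# assign formulas to a subset of a spectrum's peaks, keeping original
# peak indices
assign_peak_subset <- function(spectrum, idx, config) {
  if (!length(idx)) {
    return(assign_formulas(mass_spectrum(numeric(0), numeric(0)), config))
  }
  sub <- mass_spectrum(spectrum$peaks$mz[idx], spectrum$peaks$intensity[idx],
                       sample_id = spectrum$sample_id,
                       polarity = spectrum$polarity)
  asg <- assign_formulas(sub, config)
  # sub is sorted like idx (idx drawn from a sorted spectrum)
  asg$peak_idx <- idx[asg$peak_idx]
  asg
}

# filtered H/D-exchange series of one spectrum, bases formula-assigned
hd_series_assigned <- function(spectrum, config) {
  ser <- detect_series(spectrum, "HD_EXCHANGE", tol_mz = config$tol_mz,
                       k_max = config$k_max)
  if (!nrow(ser)) return(ser)
  asg <- assign_peak_subset(spectrum, sort(unique(ser$base_idx)),
                            config$assignment)
  filter_series(ser, asg)
}

#' Detect D-labeled exogenous components for one administration route
#'
#' Runs H/D-exchange series detection on every labeled-administration
#' spectrum of the route. A component record is emitted for a base formula
#' when (i) a chemically feasible series with an assigned unlabeled base
#' exists, (ii) no series base at the same m/z (within tolerance) appears
#' in any control spectrum, and (iii) regardless of whether the base
#' matches the labeled reference material — that match is recorded in
#' `in_labeled_ref` rather than used as a gate, since reference spectra can
#' miss genuine components for ionization-suppression reasons.
#'
#' @param sset A [sample_set()].
#' @param route `"parenteral"` or `"oral"`.
#' @param config A [derep_config()].
#' @return Data frame of class `component_records`: `formula`, `c`, `h`,
#'   `o`, `d`, `br`, `routes` (list column), `n_support`, `in_labeled_ref`,
#'   `n_exchangeable`, `base_mz`, `evidence` (list column of series ids).
#' @export
detect_exogenous <- function(sset, route, config = derep_config()) {
  if (is.null(sset$labeled_admin[[route]]) ||
      !length(sset$labeled_admin[[route]])) {
    stop("no labeled_admin spectra for route '", route, "'")
  }
  control_bases <- sort(unlist(lapply(sset$control, function(sp) {
    detect_series(sp, "HD_EXCHANGE", config$tol_mz, config$k_max)$base_mz
  })))
  ref_bases <- sort(unlist(lapply(sset$labeled_ref, function(sp) {
    detect_series(sp, "HD_EXCHANGE", config$tol_mz, config$k_max)$base_mz
  })))
  near_any <- function(x, tab) {
    if (!length(tab) || !length(x)) return(rep(FALSE, length(x)))
    !is.na(nearest_peak_idx(tab, x, config$tol_mz))
  }
  per_rep <- lapply(sset$labeled_admin[[route]], function(sp) {
    fs <- hd_series_assigned(sp, config)
    if (!nrow(fs)) return(NULL)
    fs <- fs[!near_any(fs$base_mz, control_bases), , drop = FALSE]
    if (!nrow(fs)) return(NULL)
    fs$in_ref <- near_any(fs$base_mz, ref_bases)
    fs
  })
  per_rep <- per_rep[!vapply(per_rep, is.null, logical(1))]
  if (!length(per_rep)) return(empty_component_records())
  all_hits <- do.call(rbind, lapply(per_rep, function(fs) {
    data.frame(formula = fs$formula, c = fs$c, h = fs$h, o = fs$o,
               max_k = fs$max_k, base_mz = fs$base_mz, in_ref = fs$in_ref,
               series_id = fs$series_id)
  }))
  by_formula <- split(all_hits, all_hits$formula)
  recs <- do.call(rbind, lapply(by_formula, function(g) {
    data.frame(
      formula = g$formula[1L], c = g$c[1L], h = g$h[1L], o = g$o[1L],
      d = 0L, br = 0L,
      n_support = nrow(g),
      in_labeled_ref = any(g$in_ref),
      n_exchangeable = max(g$max_k),
      base_mz = stats::median(g$base_mz)
    )
  }))
  recs$routes <- rep(list(route), nrow(recs))
  recs$evidence <- lapply(by_formula, function(g) unique(g$series_id))
  rownames(recs) <- NULL
  class(recs) <- base::c("component_records", "data.frame")
  recs
}

empty_component_records <- function() {
  recs <- data.frame(
    formula = character(), c = integer(), h = integer(), o = integer(),
    d = integer(), br = integer(), n_support = integer(),
    in_labeled_ref = logical(), n_exchangeable = integer(),
    base_mz = numeric()
  )
  recs$routes <- list()
  recs$evidence <- list()
  class(recs) <- base::c("component_records", "data.frame")
  recs
}

#' Merge per-route component records
#'
#' Union keyed by formula: routes are unioned, replicate support takes the
#' per-route maximum, `in_labeled_ref` is true when any route observed the
#' reference match, and the observed exchange count takes the maximum.
#' Idempotent and commutative in route order.
#'
#' @param per_route List of `component_records` tables (one per route, any
#'   order; a single merged table may also be passed through).
#' @return A merged `component_records` table, sorted by formula.
#' @export
merge_routes <- function(per_route) {
  if (inherits(per_route, "data.frame")) per_route <- list(per_route)
  per_route <- per_route[vapply(per_route, nrow, integer(1)) > 0]
  if (!length(per_route)) return(empty_component_records())
  all <- do.call(rbind, per_route)
  by_formula <- split(seq_len(nrow(all)), all$formula)
  recs <- do.call(rbind, lapply(by_formula, function(ix) {
    g <- all[ix, , drop = FALSE]
    data.frame(
      formula = g$formula[1L], c = g$c[1L], h = g$h[1L], o = g$o[1L],
      d = 0L, br = 0L,
      n_support = max(g$n_support),
      in_labeled_ref = any(g$in_labeled_ref),
      n_exchangeable = max(g$n_exchangeable),
      base_mz = stats::median(g$base_mz)
    )
  }))
  recs$routes <- lapply(by_formula, function(ix) {
    sort(unique(unlist(all$routes[ix])))
  })
  recs$evidence <- lapply(by_formula, function(ix) {
    unique(unlist(all$evidence[ix]))
  })
  recs <- recs[order(recs$formula), , drop = FALSE]
  rownames(recs) <- NULL
  class(recs) <- base::c("component_records", "data.frame")
  recs
}

#' Final filtration of merged component records
#'
#' Conjunctive criteria, each individually switchable through the config:
#' minimum replicate support, presence in the labeled reference material,
#' and H/C and O/C windows. Per-criterion attrition is recorded in the
#' `attrition` attribute so any filtration scheme's effect is observable.
#'
#' @param records A `component_records` table.
#' @param config A [derep_config()].
#' @return The surviving subset (always a subset of the input), with
#'   attribute `attrition`: data frame `criterion`, `n_removed`,
#'   `n_remaining`.
#' @export
final_filter <- function(records, config = derep_config()) {
  att <- data.frame(criterion = character(), n_removed = integer(),
                    n_remaining = integer())
  apply_crit <- function(recs, name, keep) {
    att <<- rbind(att, data.frame(criterion = name,
                                  n_removed = sum(!keep),
                                  n_remaining = sum(keep)))
    recs[keep, , drop = FALSE]
  }
  out <- records
  if (nrow(out)) {
    out <- apply_crit(out, "min_support", out$n_support >= config$min_support)
  }
  if (nrow(out) && config$require_labeled_ref) {
    out <- apply_crit(out, "in_labeled_ref", out$in_labeled_ref)
  }
  if (nrow(out)) {
    hc <- hc_ratio(out)
    out <- apply_crit(out, "hc_range",
                      hc >= config$hc_range[1] & hc <= config$hc_range[2])
  }
  if (nrow(out)) {
    oc <- oc_ratio(out)
    out <- apply_crit(out, "oc_range",
                      oc >= config$oc_range[1] & oc <= config$oc_range[2])
  }
  rownames(out) <- NULL
  attr(out, "attrition") <- att
  class(out) <- base::c("component_records", "data.frame")
  out
}

#' Aggregate functional-group descriptors from tag experiments
#'
#' For each component record, series of each tagging reaction
#' (deuteromethylation, reduction, bromination, and optionally H/D
#' exchange) are located in the corresponding chemically tagged
#' parent-material spectrum and folded into a descriptor via
#' [descriptors_from_series()]. A completeness flag marks records for which
#' all three structural descriptors (carboxyl count, carbonyl count,
#' aromaticity) are known.
#'
#' @param records A `component_records` table.
#' @param tag_experiments Named list mapping reaction names to a
#'   `mass_spectrum` of the tagged parent material (or a list of replicate
#'   spectra; the first is used).
#' @param config A [derep_config()].
#' @return `records` with columns `n_cooh`, `n_carbonyl`, `is_aromatic`,
#'   `descriptor_complete` appended (`n_exchangeable` is refreshed when an
#'   H/D experiment is supplied).
#' @export
aggregate_descriptors <- function(records, tag_experiments,
                                  config = derep_config()) {
  run <- names(tag_experiments)
  series_by_rxn <- lapply(run, function(rxn) {
    sp <- tag_experiments[[rxn]]
    if (is.list(sp) && !inherits(sp, "mass_spectrum")) sp <- sp[[1L]]
    ser <- detect_series(sp, rxn, config$tol_mz, config$k_max)
    if (!nrow(ser)) return(ser)
    asg <- assign_peak_subset(sp, sort(unique(ser$base_idx)),
                              config$assignment)
    filter_series(ser, asg)
  })
  names(series_by_rxn) <- run
  n <- nrow(records)
  records$n_cooh <- rep(NA_integer_, n)
  records$n_carbonyl <- rep(NA_integer_, n)
  records$is_aromatic <- rep(NA, n)
  records$descriptor_complete <- rep(FALSE, n)
  for (i in seq_len(n)) {
    per_rxn <- lapply(run, function(rxn) {
      fs <- series_by_rxn[[rxn]]
      if (!nrow(fs)) return(NULL)
      hit <- fs[fs$formula == records$formula[i], , drop = FALSE]
      if (!nrow(hit)) return(NULL)
      hit
    })
    names(per_rxn) <- run
    dsc <- descriptors_from_series(records[i, base::c("c", "h", "o", "d", "br")],
                                   per_rxn, experiments_run = run)
    records$n_cooh[i] <- dsc$n_cooh
    records$n_carbonyl[i] <- dsc$n_carbonyl
    records$is_aromatic[i] <- dsc$is_aromatic
    if (!is.na(dsc$n_exchangeable)) {
      records$n_exchangeable[i] <- dsc$n_exchangeable
    }
    records$descriptor_complete[i] <- dsc$complete
  }
  records
}

#' Run the complete dereplication pipeline
#'
#' Detects exogenous components for every route present in the sample set,
#' merges routes, applies final filtration, and (when tag experiments are
#' given) aggregates functional descriptors. The returned report carries
#' the component counts at every pipeline stage.
#'
#' @param sset A [sample_set()].
#' @param tag_experiments Optional named list of tagged parent-material
#'   spectra, see [aggregate_descriptors()].
#' @param config A [derep_config()].
#' @return List with `components` (final `component_records`) and `report`
#'   (named list of per-stage counts, JSON-serialisable).
#' @export
run_dereplication <- function(sset, tag_experiments = NULL,
                              config = derep_config()) {
  routes <- names(sset$labeled_admin)
  per_route <- lapply(routes, function(r) detect_exogenous(sset, r, config))
  names(per_route) <- routes
  merged <- merge_routes(per_route)
  final <- final_filter(merged, config)
  report <- list(
    per_route = as.list(stats::setNames(
      vapply(per_route, nrow, integer(1)), routes
    )),
    merged_unique = nrow(merged),
    final = nrow(final),
    attrition = attr(final, "attrition")
  )
  if (!is.null(tag_experiments)) {
    final <- aggregate_descriptors(final, tag_experiments, config)
    report$descriptor_complete <- sum(final$descriptor_complete)
  }
  list(components = final, report = report)
}

#' Export component records as CSV
#'
#' @param records A `component_records` table.
#' @param path Output CSV path.
#' @return The flattened data frame, invisibly.
#' @export
write_components <- function(records, path) {
  df <- as.data.frame(records)
  df$routes <- vapply(records$routes, paste, character(1), collapse = ";")
  df$evidence <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Read a component table written by [write_components()]
#'
#' @param path CSV path.
#' @return A `component_records`-like data frame (routes as `;`-separated
#'   strings converted back to list column).
#' @export
read_components <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$routes <- strsplit(df$routes, ";", fixed = TRUE)
  class(df) <- base::c("component_records", "data.frame")
  df
}
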
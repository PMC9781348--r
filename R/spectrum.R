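#' Construct a centroided mass spectrum
#'
#' Peaks are sorted by ascending m/z; peaks closer than `merge_tol` Th are
#' merged by summing their intensities (keeping the intensity-weighted m/z of
#' the first occurrence's position is unnecessary at 1e-6 Th — the lower m/z
#' is kept).
#'
#' @param mz Numeric vector of m/z values (Th), all > 0.
#' @param intensity Numeric vector of non-negative abundances.
#' @param sample_id Sample identifier string.
#' @param polarity `"negative"` (default) or `"positive"`.
#' @param metadata Free-form named list (route, fraction solvent, replicate,
#'   source path, ...).
#' @param merge_tol Duplicate-m/z merge tolerance in Th.
#' @return An object of class `mass_spectrum`: a list with elements `peaks`
#'   (data frame `mz`, `intensity`), `sample_id`, `polarity`, `metadata`.
#' @export
#' @examples
#' mass_spectrum(c(121.0295, 93.0346), c(100, 50), sample_id = "s1")
mass_spectrum <- function(mz, intensity, sample_id = "", polarity = "negative",
                          metadata = list(), merge_tol = 1e-6) {
  if (length(mz) != length(intensity)) {
    stop("mz and intensity lengths differ")
  }
  if (any(!is.finite(mz)) || any(!is.finite(intensity))) {
    stop("non-finite m/z or intensity")
  }
  if (any(mz <= 0)) stop("m/z values must be positive")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  ord <- order(mz)
  mz <- mz[ord]
  intensity <- intensity[ord]
  if (length(mz) > 1L) {
    grp <- cumsum(base::c(TRUE, diff(mz) > merge_tol))
    if (max(grp) < length(mz)) {
      intensity <- as.numeric(tapply(intensity, grp, sum))
      mz <- as.numeric(tapply(mz, grp, function(x) x[1L]))
    }
  }
  structure(
    list(
      peaks = data.frame(mz = mz, intensity = intensity),
      sample_id = sample_id,
      polarity = match.arg(polarity, base::c("negative", "positive")),
      metadata = metadata
    ),
    class = "mass_spectrum"
  )
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat("<mass_spectrum> ", x$sample_id, ": ", nrow(x$peaks), " peaks, ",
      x$polarity, " mode\n", sep = "")
  invisible(x)
}

#' Number of peaks in a spectrum
#' @param spectrum A `mass_spectrum`.
#' @return Integer peak count.
#' @export
n_peaks <- function(spectrum) nrow(spectrum$peaks)

#' Relative peak intensities
#'
#' Intensities divided by the spectrum's total ion intensity. Computed on
#' demand; the stored spectrum is never modified.
#'
#' @param spectrum A `mass_spectrum`.
#' @return Numeric vector summing to 1 (or empty).
#' @export
relative_intensity <- function(spectrum) {
  tot <- sum(spectrum$peaks$intensity)
  if (tot <= 0) return(rep(0, nrow(spectrum$peaks)))
  spectrum$peaks$intensity / tot
}

#' Column mapping for delimited peak lists
#'
#' @param sep Field separator; `NULL` auto-detects tab vs comma from the
#'   first line.
#' @param mz_col,intensity_col Column names (when the file has a header) or
#'   1-based column indices (when it does not).
#' @param header Logical; `NA` auto-detects by testing whether the first
#'   line's fields are numeric.
#' @return A list of class `peaklist_dialect`.
#' @export
peaklist_dialect <- function(sep = NULL, mz_col = "mz",
                             intensity_col = "intensity", header = NA) {
  structure(list(sep = sep, mz_col = mz_col, intensity_col = intensity_col,
                 header = header),
            class = "peaklist_dialect")
}

#' Read a centroided peak list from delimited text
#'
#' Expects at least an m/z and an intensity column. Peaks are sorted and
#' de-duplicated (m/z within 1e-6 Th merged, intensities summed). The source
#' path is recorded in the spectrum metadata. Parse failures name the
#' offending line.
#'
#' @param path File path.
#' @param dialect A [peaklist_dialect()].
#' @param sample_id Sample identifier; defaults to the file name.
#' @param polarity Ion mode of the spectrum.
#' @param metadata Extra metadata entries.
#' @return A `mass_spectrum`.
#' @export
read_peaklist <- function(path, dialect = peaklist_dialect(),
                          sample_id = NULL, polarity = "negative",
                          metadata = list()) {
  if (!file.exists(path)) stop("peak list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty peak list: ", path)
  sep <- dialect$sep
  if (is.null(sep)) {
    sep <- if (grepl("\t", lines[1L])) "\t" else ","
  }
  fields <- strsplit(lines, sep, fixed = TRUE)
  first_numeric <- !any(is.na(suppressWarnings(as.numeric(fields[[1L]]))))
  header <- dialect$header
  if (is.na(header)) header <- !first_numeric
  col_idx <- function(col, fallback) {
    if (is.numeric(col)) return(as.integer(col))
    if (!header) return(fallback)  # headerless: positional columns
    i <- match(col, trimws(fields[[1L]]))
    if (is.na(i)) stop("missing column '", col, "' in ", path)
    i
  }
  i_mz <- col_idx(dialect$mz_col, 1L)
  i_int <- col_idx(dialect$intensity_col, 2L)
  body_at <- if (header) 2L else 1L
  if (body_at > length(lines)) stop("no data rows in ", path)
  rows <- fields[body_at:length(fields)]
  lineno <- seq(body_at, length(fields))
  get_num <- function(i, what) {
    raw <- vapply(rows, function(r) {
      if (length(r) < i) NA_character_ else trimws(r[[i]])
    }, character(1))
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val))
    if (length(bad)) {
      stop("non-numeric ", what, " at line ", lineno[bad[1L]], " of ", path,
           ": '", raw[bad[1L]], "'")
    }
    val
  }
  mz <- get_num(i_mz, "m/z")
  intensity <- get_num(i_int, "intensity")
  if (is.null(sample_id)) sample_id <- basename(path)
  metadata$source <- path
  mass_spectrum(mz, intensity, sample_id = sample_id, polarity = polarity,
                metadata = metadata)
}

#' Write a spectrum as a delimited peak list
#'
#' m/z is written with six decimal places of precision retained (round-trips
#' to 1e-6 Th); intensities with six significant digits.
#'
#' @param spectrum A `mass_spectrum`.
#' @param path Output file path.
#' @param sep Field separator.
#' @return The path, invisibly.
#' @export
write_peaklist <- function(spectrum, path, sep = "\t") {
  df <- data.frame(
    mz = sprintf("%.6f", spectrum$peaks$mz),
    intensity = formatC(spectrum$peaks$intensity, digits = 6, format = "g")
  )
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

# index of the nearest element of sorted `mz` to each target, NA when the
# nearest is farther than tol; exact ties break toward the lower m/z
nearest_peak_idx <- function(mz, targets, tol) {
  n <- length(mz)
  if (n == 0L || length(targets) == 0L) {
    return(rep(NA_integer_, length(targets)))
  }
  i <- findInterval(targets, mz)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, n)
  dlo <- abs(mz[lo] - targets)
  dhi <- abs(mz[hi] - targets)
  dlo[i < 1L] <- Inf
  pick <- ifelse(dlo <= dhi, lo, hi)
  dist <- pmin(dlo, dhi)
  pick[dist > tol] <- NA_integer_
  as.integer(pick)
}

#' Match peaks across two spectra
#'
#' Greedy one-to-one matching by smallest absolute m/z difference within
#' `tol_mz`: candidate pairs are ranked by |dmz| and accepted while both
#' peaks are still unused. The output partitions both inputs.
#'
#' @param a,b `mass_spectrum` objects.
#' @param tol_mz Matching tolerance in Th (> 0).
#' @return A list with `matches` (data frame `idx_a`, `idx_b`, `mz_a`,
#'   `mz_b`, `dmz`), `unmatched_a`, `unmatched_b` (integer peak indices).
#' @export
match_peaks <- function(a, b, tol_mz) {
  stopifnot(tol_mz > 0)
  mza <- a$peaks$mz
  mzb <- b$peaks$mz
  na <- length(mza)
  nb <- length(mzb)
  if (na == 0L || nb == 0L) {
    return(list(
      matches = data.frame(idx_a = integer(), idx_b = integer(),
                           mz_a = numeric(), mz_b = numeric(),
                           dmz = numeric()),
      unmatched_a = seq_len(na), unmatched_b = seq_len(nb)
    ))
  }
  lo <- findInterval(mza - tol_mz, mzb) + 1L
  hi <- findInterval(mza + tol_mz, mzb)
  reps <- pmax(hi - lo + 1L, 0L)
  idx_a <- rep.int(seq_len(na), reps)
  idx_b <- unlist(lapply(seq_len(na), function(i) {
    if (reps[i] > 0L) seq(lo[i], hi[i]) else integer()
  }), use.names = FALSE)
  if (!length(idx_a)) {
    return(list(
      matches = data.frame(idx_a = integer(), idx_b = integer(),
                           mz_a = numeric(), mz_b = numeric(),
                           dmz = numeric()),
      unmatched_a = seq_len(na), unmatched_b = seq_len(nb)
    ))
  }
  dmz <- abs(mza[idx_a] - mzb[idx_b])
  ord <- order(dmz, idx_a, idx_b)
  used_a <- logical(na)
  used_b <- logical(nb)
  keep <- logical(length(ord))
  for (k in ord) {
    ia <- idx_a[k]
    ib <- idx_b[k]
    if (!used_a[ia] && !used_b[ib]) {
      used_a[ia] <- TRUE
      used_b[ib] <- TRUE
      keep[k] <- TRUE
    }
  }
  m <- data.frame(
    idx_a = idx_a[keep], idx_b = idx_b[keep],
    mz_a = mza[idx_a[keep]], mz_b = mzb[idx_b[keep]],
    dmz = mza[idx_a[keep]] - mzb[idx_b[keep]]
  )
  m <- m[order(m$idx_a), , drop = FALSE]
  rownames(m) <- NULL
  list(
    matches = m,
    unmatched_a = which(!used_a),
    unmatched_b = which(!used_b)
  )
}
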
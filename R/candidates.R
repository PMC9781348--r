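#' Read / write SMILES files (one structure per line)
#'
#' @param path File path.
#' @return Character vector of SMILES strings (blank lines dropped).
#' @export
read_smiles_file <- function(path) {
  x <- readLines(path, warn = FALSE)
  trimws(x[nzchar(trimws(x))])
}

#' @rdname read_smiles_file
#' @param smiles Character vector of SMILES strings.
#' @export
write_smiles_file <- function(smiles, path) {
  writeLines(smiles, path)
  invisible(path)
}

# strip stereo annotations from SMILES text (wedge bonds and chirality tags)
strip_stereo <- function(smiles) {
  gsub("[/\\\\]", "", gsub("@", "", smiles, fixed = TRUE))
}

# batch-canonicalize SMILES via OpenBabel; returns canonical SMILES or NA
# for strings OpenBabel rejects. A malformed string can abort the remainder
# of an OpenBabel input stream, so conversion runs in chunks and entries
# missing from a chunk's output are retried one at a time.
canonical_smiles <- function(smiles) {
  n <- length(smiles)
  if (!n) return(character(0))
  res <- rep(NA_character_, n)
  convert <- function(idx) {
    tagged <- paste(smiles[idx], idx)
    out <- suppressWarnings(tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN",
                                paste(tagged, collapse = "\n")),
      error = function(e) ""
    ))
    lines <- strsplit(out, "\n", fixed = TRUE)[[1L]]
    for (ln in lines[nzchar(lines)]) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(parts) >= 2L) {
        i <- suppressWarnings(as.integer(parts[2L]))
        if (!is.na(i)) res[i] <<- parts[1L]
      }
    }
  }
  for (ch in split(seq_len(n), ceiling(seq_len(n) / 500))) convert(ch)
  for (i in which(is.na(res))) convert(i)
  res
}

# parse an OpenBabel formula string like "C7H6O3" into CHO counts; returns
# NULL for formulas containing other elements
cho_counts <- function(formula_string) {
  parts <- regmatches(
    formula_string,
    gregexpr("([A-Z][a-z]?)([0-9]*)", formula_string)
  )[[1L]]
  out <- base::c(C = 0L, H = 0L, O = 0L)
  for (p in parts) {
    sym <- sub("[0-9]*$", "", p)
    num <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(num)) as.integer(num) else 1L
    if (!sym %in% names(out)) return(NULL)
    out[sym] <- out[sym] + n
  }
  out
}

#' Standardize raw structure strings
#'
#' Invalid SMILES are dropped (and counted), stereochemistry is stripped,
#' structures are canonicalized with OpenBabel, and duplicates by canonical
#' form are removed.
#'
#' @param raw Character vector of structure strings.
#' @return Data frame of class `candidate_structures` with columns
#'   `smiles` (canonical), `formula`, `c`, `h`, `o`, `is_cho`; attribute
#'   `counts` = list(`n_input`, `n_valid`, `n_unique`).
#' @export
#' @examples
#' \donttest{
#' standardize_candidates(c("c1ccccc1O", "Oc1ccccc1", "not_a_smiles"))
#' }
standardize_candidates <- function(raw) {
  n_input <- length(raw)
  can <- canonical_smiles(strip_stereo(raw))
  valid <- can[!is.na(can)]
  n_valid <- length(valid)
  uniq <- unique(valid)
  if (length(uniq)) {
    props <- lapply(uniq, function(s) {
      mol <- ChemmineOB::forEachMol("SMILES", s, identity)
      ChemmineOB::prop_OB(mol)
    })
    fstr <- vapply(props, function(p) p$formula, character(1))
    cnt <- lapply(fstr, cho_counts)
    is_cho <- !vapply(cnt, is.null, logical(1))
    cc <- vapply(cnt, function(x) if (is.null(x)) NA_integer_ else x[["C"]],
                 integer(1))
    hh <- vapply(cnt, function(x) if (is.null(x)) NA_integer_ else x[["H"]],
                 integer(1))
    oo <- vapply(cnt, function(x) if (is.null(x)) NA_integer_ else x[["O"]],
                 integer(1))
  } else {
    fstr <- character(0)
    is_cho <- logical(0)
    cc <- hh <- oo <- integer(0)
  }
  out <- data.frame(
    smiles = uniq, formula = fstr, c = cc, h = hh, o = oo, is_cho = is_cho,
    stringsAsFactors = FALSE
  )
  attr(out, "counts") <- list(n_input = n_input, n_valid = n_valid,
                              n_unique = length(uniq))
  class(out) <- base::c("candidate_structures", "data.frame")
  out
}

# SMARTS patterns for the functional groups the labeling chemistry reports
.GROUP_SMARTS <- list(
  carboxyl = "[CX3](=O)[OX2H1]",
  hydroxyl_all = "[OX2H1]",
  ketone = "[#6][CX3](=O)[#6]",
  aldehyde = "[CX3H1](=O)[#6]"
)

# count aromatic ring systems (fused aromatic rings merged) of one SDF entry
aromatic_ring_systems <- function(ring_info) {
  rings <- ring_info$RINGS[ring_info$AROMATIC]
  if (!length(rings)) return(0L)
  # union-find over rings sharing atoms
  comp <- seq_along(rings)
  for (i in seq_along(rings)) {
    for (j in seq_len(i - 1L)) {
      if (length(intersect(rings[[i]], rings[[j]]))) {
        comp[comp == comp[i]] <- comp[j]
      }
    }
  }
  length(unique(comp))
}

#' Count labeling-relevant functional groups of structures
#'
#' Counts, per structure: carboxyl groups (`C(=O)OH`), hydroxyls (O-H not
#' part of a carboxyl — phenolic and alcoholic alike), carbonyls (ketone or
#' aldehyde `C=O`, excluding carboxyls and esters), and aromatic ring
#' systems (fused aromatic rings count once).
#'
#' @param smiles Character vector of (canonical) SMILES strings.
#' @return Data frame `smiles`, `carboxyl`, `hydroxyl`, `carbonyl`,
#'   `aromatic_rings`.
#' @export
#' @examples
#' \donttest{
#' count_groups("OC(=O)c1ccccc1O")  # salicylic acid
#' }
count_groups <- function(smiles) {
  if (!length(smiles)) {
    return(data.frame(smiles = character(), carboxyl = integer(),
                      hydroxyl = integer(), carbonyl = integer(),
                      aromatic_rings = integer()))
  }
  counts <- function(s) {
    mol <- tryCatch(ChemmineOB::forEachMol("SMILES", s, identity),
                    error = function(e) NULL)
    if (is.null(mol)) stop("invalid structure: ", s)
    one <- function(p) {
      as.integer(ChemmineOB::smartsSearch_OB(mol, p, uniqueMatches = TRUE))
    }
    cooh <- one(.GROUP_SMARTS$carboxyl)
    oh <- one(.GROUP_SMARTS$hydroxyl_all) - cooh
    co <- one(.GROUP_SMARTS$ketone) + one(.GROUP_SMARTS$aldehyde)
    base::c(carboxyl = cooh, hydroxyl = oh, carbonyl = co)
  }
  mat <- t(vapply(smiles, counts, integer(3)))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(
    stats::setNames(smiles, seq_along(smiles))
  ))
  ring_info <- ChemmineR::rings(sdf, upper = 20, type = "all", arom = TRUE)
  # rings() returns a flat list for a single compound
  if (length(smiles) == 1L) ring_info <- list(ring_info)
  arom <- vapply(ring_info, aromatic_ring_systems, integer(1))
  data.frame(
    smiles = smiles,
    carboxyl = mat[, "carboxyl"],
    hydroxyl = mat[, "hydroxyl"],
    carbonyl = mat[, "carbonyl"],
    aromatic_rings = arom,
    row.names = NULL
  )
}

#' Build fully annotated candidate structures
#'
#' Convenience wrapper: [standardize_candidates()] followed by
#' [count_groups()].
#'
#' @inheritParams standardize_candidates
#' @return A `candidate_structures` table with group-count columns.
#' @export
candidate_structures <- function(raw) {
  std <- standardize_candidates(raw)
  if (nrow(std)) {
    grp <- count_groups(std$smiles)
    std$carboxyl <- grp$carboxyl
    std$hydroxyl <- grp$hydroxyl
    std$carbonyl <- grp$carbonyl
    std$aromatic_rings <- grp$aromatic_rings
  } else {
    std$carboxyl <- integer()
    std$hydroxyl <- integer()
    std$carbonyl <- integer()
    std$aromatic_rings <- integer()
  }
  std
}

#' Filter candidate structures against MS-derived constraints
#'
#' Stagewise filter of annotated candidate structures against the
#' dereplicated component list:
#' \enumerate{
#'   \item ionizable: at least one -OH or -COOH group;
#'   \item moiety: at least one of an aromatic ring, a carboxyl, or a
#'     carbonyl (the three labeling-enumerated moieties);
#'   \item formula: the structure's CHO formula equals some component
#'     formula exactly;
#'   \item (strict mode only) descriptor consistency: where the matched
#'     component's descriptor is known, the structure's carboxyl count,
#'     carbonyl count and aromatic presence must equal it.
#' }
#'
#' @param candidates A `candidate_structures` table with group counts (see
#'   [candidate_structures()]).
#' @param components A `component_records` table (descriptor columns
#'   `n_cooh`, `n_carbonyl`, `is_aromatic` used in strict mode when
#'   present).
#' @param mode `"lenient"` (stages 1-3) or `"strict"` (stages 1-4).
#' @return List with `retained` (subset of `candidates`) and `report`
#'   (class `filter_report`): stage counts `n_input`, `n_valid`,
#'   `n_unique`, `n_ionizable_pass`, `n_moiety_pass`, `n_formula_match`,
#'   and in strict mode `n_descriptor_pass`.
#' @export
filter_candidates <- function(candidates, components,
                              mode = base::c("lenient", "strict")) {
  mode <- match.arg(mode)
  cnt <- attr(candidates, "counts")
  if (is.null(cnt)) {
    cnt <- list(n_input = nrow(candidates), n_valid = nrow(candidates),
                n_unique = nrow(candidates))
  }
  comp <- as.data.frame(components)
  cur <- candidates
  # stage 1: ionizable group
  cur <- cur[cur$hydroxyl + cur$carboxyl >= 1L, , drop = FALSE]
  n_ion <- nrow(cur)
  # stage 2: at least one enumerated moiety
  cur <- cur[cur$aromatic_rings >= 1L | cur$carboxyl >= 1L |
               cur$carbonyl >= 1L, , drop = FALSE]
  n_moi <- nrow(cur)
  # stage 3: exact CHO formula match against the component list
  key <- paste(comp$c, comp$h, comp$o)
  keep <- cur$is_cho & !is.na(match(paste(cur$c, cur$h, cur$o), key))
  cur <- cur[keep, , drop = FALSE]
  hit <- match(paste(cur$c, cur$h, cur$o), key)
  n_frm <- nrow(cur)
  report <- list(
    n_input = cnt$n_input, n_valid = cnt$n_valid, n_unique = cnt$n_unique,
    n_ionizable_pass = n_ion, n_moiety_pass = n_moi, n_formula_match = n_frm
  )
  if (mode == "strict") {
    ok <- rep(TRUE, nrow(cur))
    if (nrow(cur) && all(base::c("n_cooh", "n_carbonyl", "is_aromatic")
                         %in% names(comp))) {
      for (i in seq_len(nrow(cur))) {
        j <- hit[i]
        if (!is.na(comp$n_cooh[j]) && cur$carboxyl[i] != comp$n_cooh[j]) {
          ok[i] <- FALSE
        }
        if (!is.na(comp$n_carbonyl[j]) &&
            cur$carbonyl[i] != comp$n_carbonyl[j]) {
          ok[i] <- FALSE
        }
        if (!is.na(comp$is_aromatic[j]) &&
            (cur$aromatic_rings[i] >= 1L) != comp$is_aromatic[j]) {
          ok[i] <- FALSE
        }
      }
    }
    cur <- cur[ok, , drop = FALSE]
    report$n_descriptor_pass <- nrow(cur)
  }
  rownames(cur) <- NULL
  class(report) <- "filter_report"
  list(retained = cur, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  for (nm in names(x)) cat(" ", nm, ":", x[[nm]], "\n")
  invisible(x)
}
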
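#' Monoisotopic atomic masses used throughout the package
#'
#' Returns the monoisotopic atomic masses (in Da) of the elements the package
#' handles: H, D (deuterium), C, O and Br, plus the proton mass used for
#' \eqn{[M-H]^-} deprotonation.
#'
#' @return Named numeric vector with elements `H`, `D`, `C`, `O`, `Br`,
#'   `proton`.
#' @export
#' @examples
#' atomic_masses()[["H"]]
atomic_masses <- function() {
  base::c(
    H = 1.0078250319,
    D = 2.0141017780,
    C = 12,
    O = 15.9949146221,
    Br = 78.9183376,
    proton = 1.007276467
  )
}

.AM <- atomic_masses()

#' Construct a table of molecular formulae
#'
#' A `chem_formula` object is a data frame with one row per formula and
#' integer columns `c`, `h`, `o`, `d`, `br` (carbon, protium, oxygen,
#' deuterium, bromine counts). Deuterium and bromine default to zero and are
#' only populated for labeled series members. All arguments are recycled to a
#' common length.
#'
#' Validity requires at least one carbon, non-negative counts, total hydrogen
#' `h + d <= 2c + 2`, and non-negative double-bond equivalents.
#'
#' @param c,h,o,d,br Integer element counts.
#' @return A data frame of class `chem_formula`.
#' @export
#' @examples
#' chem_formula(c = 7, h = 6, o = 2)           # benzoic acid
#' chem_formula(c = 7, h = 4, o = 2, d = 2)    # its doubly D-exchanged analog
chem_formula <- function(c, h, o, d = 0L, br = 0L) {
  n <- if (length(c) == 0L) 0L else {
    max(length(c), length(h), length(o), length(d), length(br))
  }
  f <- data.frame(
    c = as.integer(rep_len(c, n)),
    h = as.integer(rep_len(h, n)),
    o = as.integer(rep_len(o, n)),
    d = as.integer(rep_len(d, n)),
    br = as.integer(rep_len(br, n))
  )
  validate_formula(f)
  class(f) <- base::c("chem_formula", "data.frame")
  f
}

validate_formula <- function(f) {
  req <- base::c("c", "h", "o", "d", "br")
  miss <- setdiff(req, names(f))
  if (length(miss)) {
    stop("formula table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (any(is.na(f$c) | is.na(f$h) | is.na(f$o) | is.na(f$d) | is.na(f$br))) {
    stop("invalid formula: missing element counts")
  }
  if (any(f$c < 1L)) stop("invalid formula: carbon count must be >= 1")
  if (any(f$h < 0L | f$o < 0L | f$d < 0L | f$br < 0L)) {
    stop("invalid formula: negative element count")
  }
  if (any(f$h + f$d > 2L * f$c + 2L)) {
    stop("invalid formula: total hydrogen exceeds 2C + 2")
  }
  if (any(f$c - (f$h + f$d + f$br) / 2 + 1 < 0)) {
    stop("invalid formula: negative double-bond equivalents")
  }
  invisible(f)
}

as_chem_formula <- function(f) {
  if (inherits(f, "chem_formula")) return(f)
  if (is.character(f)) return(parse_formula(f))
  for (col in base::c("d", "br")) if (is.null(f[[col]])) f[[col]] <- 0L
  chem_formula(f$c, f$h, f$o, f$d, f$br)
}

#' Render formulae as Hill-style strings
#'
#' @param f A `chem_formula` table (or data frame with the same columns).
#' @return Character vector like `"C7H6O2"` or `"C7H4D2O2"`.
#' @export
formula_label <- function(f) {
  f <- as_chem_formula(f)
  piece <- function(sym, n) {
    ifelse(n == 0L, "", paste0(sym, ifelse(n == 1L, "", n)))
  }
  paste0(
    piece("C", f$c), piece("H", f$h), piece("D", f$d),
    piece("O", f$o), piece("Br", f$br)
  )
}

#' Parse formula strings
#'
#' Inverse of [formula_label()]: accepts strings built from the element
#' symbols C, H, D, O, Br with optional counts.
#'
#' @param x Character vector of formula strings.
#' @return A `chem_formula` table.
#' @export
#' @examples
#' parse_formula(c("C7H6O2", "C10H8"))
parse_formula <- function(x) {
  if (!length(x)) {
    return(chem_formula(integer(0), integer(0), integer(0)))
  }
  counts <- function(s) {
    m <- gregexpr("(Br|C|H|D|O)([0-9]*)", s)[[1]]
    if (m[1] == -1L || sum(attr(m, "match.length")) != nchar(s)) {
      stop("cannot parse formula string: ", s)
    }
    parts <- regmatches(s, gregexpr("(Br|C|H|D|O)([0-9]*)", s))[[1]]
    out <- base::c(C = 0L, H = 0L, D = 0L, O = 0L, Br = 0L)
    for (p in parts) {
      sym <- sub("[0-9]*$", "", p)
      num <- sub("^(Br|C|H|D|O)", "", p)
      out[sym] <- out[sym] + if (nzchar(num)) as.integer(num) else 1L
    }
    out
  }
  tab <- t(vapply(x, counts, integer(5)))
  chem_formula(tab[, "C"], tab[, "H"], tab[, "O"], tab[, "D"], tab[, "Br"])
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", nrow(x), " formula(e)\n", sep = "")
  df <- as.data.frame(x)
  df$label <- formula_label(x)
  print(utils::head(df, 10))
  if (nrow(df) > 10) cat("... and", nrow(df) - 10, "more rows\n")
  invisible(x)
}

#' Neutral monoisotopic mass of a formula
#'
#' @param f A `chem_formula` table.
#' @return Numeric vector of masses in Da.
#' @export
#' @examples
#' monoisotopic_mass(chem_formula(7, 6, 2))  # 122.036779
monoisotopic_mass <- function(f) {
  f <- as_chem_formula(f)
  validate_formula(f)
  .AM[["C"]] * f$c + .AM[["H"]] * f$h + .AM[["D"]] * f$d +
    .AM[["O"]] * f$o + .AM[["Br"]] * f$br
}

#' m/z of the deprotonated molecular ion
#'
#' Only the negative-mode singly charged \eqn{[M-H]^-} ion is supported:
#' m/z = neutral mass minus the proton mass (the electron stays with the ion).
#'
#' @param f A `chem_formula` table.
#' @param polarity Ion mode; only `"negative"` is implemented.
#' @param charge Charge state; only 1 is implemented.
#' @return Numeric vector of m/z values in Th.
#' @export
#' @examples
#' mz_from_formula(chem_formula(7, 6, 2))  # 121.029503
mz_from_formula <- function(f, polarity = "negative", charge = 1L) {
  if (!identical(polarity, "negative") || charge != 1L) {
    stop("only singly charged negative-mode [M-H]- ions are supported")
  }
  monoisotopic_mass(f) - .AM[["proton"]]
}

#' Neutral mass corresponding to an observed m/z
#'
#' @param mz Observed m/z values (Th).
#' @inheritParams mz_from_formula
#' @return Neutral monoisotopic masses in Da.
#' @export
neutral_mass_from_mz <- function(mz, polarity = "negative", charge = 1L) {
  if (!identical(polarity, "negative") || charge != 1L) {
    stop("only singly charged negative-mode [M-H]- ions are supported")
  }
  mz + .AM[["proton"]]
}

#' Double-bond equivalents
#'
#' DBE = C - (H + D + Br)/2 + 1. Deuterium and bromine count as hydrogen
#' substituents, so labeling never changes a compound's DBE.
#'
#' @param f A `chem_formula` table.
#' @return Numeric vector of DBE values (integer or half-integer, >= 0).
#' @export
dbe <- function(f) {
  f <- as_chem_formula(f)
  f$c - (f$h + f$d + f$br) / 2 + 1
}

#' Atomic ratios
#'
#' O/C and H/C ratios of a formula. Deuterium counts as hydrogen so that
#' labeling does not move a compound in van Krevelen space.
#'
#' @param f A `chem_formula` table.
#' @return Numeric vector.
#' @export
oc_ratio <- function(f) {
  f <- as_chem_formula(f)
  f$o / f$c
}

#' @rdname oc_ratio
#' @export
hc_ratio <- function(f) {
  f <- as_chem_formula(f)
  (f$h + f$d) / f$c
}

#' Aromaticity index of a CHO formula
#'
#' The CHO-restricted aromaticity index
#' AI = (1 + C - O - 0.5 H) / (C - O), with H the total hydrogen count
#' (protium + deuterium) and bromine ignored. Degenerate cases (denominator
#' <= 0 or negative numerator) are clamped to 0.
#'
#' @param f A `chem_formula` table.
#' @return Numeric vector in \[0, Inf); typically \[0, 1\].
#' @export
#' @examples
#' aromaticity_index(parse_formula(c("C10H8", "C7H6O2", "C6H12O6")))
aromaticity_index <- function(f) {
  f <- as_chem_formula(f)
  num <- 1 + f$c - f$o - 0.5 * (f$h + f$d)
  den <- f$c - f$o
  ai <- ifelse(den <= 0 | num < 0, 0, num / den)
  ai
}

#' Compound-class thresholds
#'
#' The default rule set used by [compound_class()]: a formula is LIPID_LIKE
#' when H/C >= 1.7 and O/C <= 0.25 (saturated, oxygen-poor — unlikely
#' indigenous to a polyphenolic material); otherwise ALIPHATIC when
#' H/C >= 1.5; otherwise CONDENSED_AROMATIC when AI >= 0.67, AROMATIC when
#' AI > 0.5, UNSATURATED below.
#'
#' @param ai_condensed,ai_aromatic AI cut-offs.
#' @param hc_aliphatic H/C cut-off for aliphatic compounds.
#' @param hc_lipid,oc_lipid Lipid-rule cut-offs.
#' @return Named list of thresholds.
#' @export
class_thresholds <- function(ai_condensed = 0.67, ai_aromatic = 0.5,
                             hc_aliphatic = 1.5, hc_lipid = 1.7,
                             oc_lipid = 0.25) {
  list(
    ai_condensed = ai_condensed, ai_aromatic = ai_aromatic,
    hc_aliphatic = hc_aliphatic, hc_lipid = hc_lipid, oc_lipid = oc_lipid
  )
}

#' Compound classes recognised by the package
#' @export
compound_classes <- function() {
  base::c("CONDENSED_AROMATIC", "AROMATIC", "UNSATURATED", "ALIPHATIC",
          "LIPID_LIKE")
}

#' Classify formulae by atomic ratios and aromaticity index
#'
#' Every valid formula receives exactly one class label; see
#' [class_thresholds()] for the rule order. Classification uses total
#' hydrogen, so it is invariant to H/D relabeling.
#'
#' @param f A `chem_formula` table.
#' @param thresholds A list from [class_thresholds()].
#' @return Character vector of class labels (see [compound_classes()]).
#' @export
#' @examples
#' compound_class(parse_formula(c("C18H36O2", "C10H8", "C7H6O2")))
compound_class <- function(f, thresholds = class_thresholds()) {
  f <- as_chem_formula(f)
  hc <- hc_ratio(f)
  oc <- oc_ratio(f)
  ai <- aromaticity_index(f)
  th <- thresholds
  cls <- rep("UNSATURATED", nrow(f))
  cls[ai > th$ai_aromatic] <- "AROMATIC"
  cls[ai >= th$ai_condensed] <- "CONDENSED_AROMATIC"
  cls[hc >= th$hc_aliphatic] <- "ALIPHATIC"
  cls[hc >= th$hc_lipid & oc <= th$oc_lipid] <- "LIPID_LIKE"
  cls
}

#' The four labeling reactions and their per-event mass shifts
#'
#' Each labeling chemistry shifts a molecule's mass by a fixed amount per
#' reaction event; the length of the resulting peak series reports a
#' structural descriptor:
#' \describe{
#'   \item{HD_EXCHANGE}{D replaces H; counts exchangeable hydrogens.}
#'   \item{DEUTEROMETHYLATION}{OCD3 replaces acidic OH hydrogen; counts
#'     carboxylic groups.}
#'   \item{REDUCTION}{C=O becomes CHD-OH (deuteride reduction); counts
#'     carbonyl groups.}
#'   \item{BROMINATION}{Br replaces aromatic H (NBS); reports aromatic-ring
#'     presence.}
#' }
#'
#' @return Data frame with columns `reaction`, `delta_da`, `descriptor`.
#' @export
reactions <- function() {
  data.frame(
    reaction = base::c("HD_EXCHANGE", "DEUTEROMETHYLATION", "REDUCTION",
                       "BROMINATION"),
    delta_da = base::c(
      .AM[["D"]] - .AM[["H"]],
      .AM[["C"]] + 3 * .AM[["D"]] - .AM[["H"]],
      .AM[["H"]] + .AM[["D"]],
      .AM[["Br"]] - .AM[["H"]]
    ),
    descriptor = base::c("n_exchangeable", "n_cooh", "n_carbonyl",
                         "is_aromatic")
  )
}

# reference per-event shifts (Da) the recomputed values must agree with
.REFERENCE_SHIFTS <- base::c(
  HD_EXCHANGE = 1.00628,
  DEUTEROMETHYLATION = 17.03448,
  REDUCTION = 3.02193,
  BROMINATION = 77.91051
)

#' Mass shift per labeling event
#'
#' Recomputes the per-event shift of a labeling reaction from monoisotopic
#' atomic masses and asserts agreement with the reference constants
#' (17.03448, 3.02193, 77.91051, 1.00628 Da) to within 1e-5 Da.
#'
#' @param reaction One of `"HD_EXCHANGE"`, `"DEUTEROMETHYLATION"`,
#'   `"REDUCTION"`, `"BROMINATION"`.
#' @return The mass shift in Da per event.
#' @export
#' @examples
#' reaction_mass_shift("HD_EXCHANGE")
reaction_mass_shift <- function(reaction) {
  tab <- reactions()
  i <- match(reaction, tab$reaction)
  if (is.na(i)) stop("unknown labeling reaction: ", reaction)
  delta <- tab$delta_da[i]
  stopifnot(abs(delta - .REFERENCE_SHIFTS[[reaction]]) < 1e-5)
  delta
}

#' Element-wise sum of two formula tables
#'
#' @param a,b `chem_formula` tables of equal length.
#' @return A `chem_formula` table.
#' @export
formula_add <- function(a, b) {
  a <- as_chem_formula(a)
  b <- as_chem_formula(b)
  chem_formula(a$c + b$c, a$h + b$h, a$o + b$o, a$d + b$d, a$br + b$br)
}
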
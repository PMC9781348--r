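#' Generate a ground-truth CHO compound mixture
#'
#' Samples valid CHO formulae in a mass window together with per-compound
#' functional-group ground truth (carboxyl count, carbonyl count,
#' aromaticity, exchangeable-hydrogen count) satisfying the descriptor
#' invariants: `n_cooh <= floor(o/2)`, `n_carbonyl <= o - 2 n_cooh`,
#' `1 <= n_exchangeable <= h`. Formulae are sampled by carbon number,
#' double-bond equivalents and oxygen number, which spans the unsaturated /
#' aromatic / condensed-aromatic classes a degraded-lignin polyphenol
#' mixture covers. Identical seeds give identical output.
#'
#' @param n Number of distinct compounds (>= 1).
#' @param seed Random seed.
#' @param mass_range Neutral monoisotopic mass window in Da.
#' @param class_mix Optional named numeric of target class proportions
#'   (names from [compound_classes()]); compounds are accepted until each
#'   class quota is filled.
#' @return A data frame of class `ground_truth`: formula columns, `formula`
#'   label, `mass`, `class`, `n_cooh`, `n_carbonyl`, `is_aromatic`,
#'   `n_exchangeable`, `smiles` (NA; structures are optional); attributes
#'   `seed` and `params`.
#' @export
#' @examples
#' generate_mixture(5, seed = 1)
generate_mixture <- function(n, seed, mass_range = base::c(150, 800),
                             class_mix = NULL) {
  stopifnot(n >= 1L, length(mass_range) == 2L, mass_range[1] < mass_range[2])
  set.seed(seed)
  if (!is.null(class_mix)) {
    if (is.null(names(class_mix)) ||
        !all(names(class_mix) %in% compound_classes())) {
      stop("class_mix must be named by compound classes")
    }
    quota <- round(class_mix / sum(class_mix) * n)
    # rounding may under-fill; top up the largest class
    quota[which.max(quota)] <- quota[which.max(quota)] + (n - sum(quota))
  }
  picked <- list()
  labels <- character(0)
  filled <- stats::setNames(integer(length(compound_classes())),
                            compound_classes())
  attempts <- 0L
  max_attempts <- 2000L * n
  while (length(picked) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("infeasible generation constraints: produced ", length(picked),
           " of ", n, " compounds")
    }
    cc <- sample(6:40, 1L)
    # DBE biased toward the aromatic-rich midrange typical of degraded
    # lignin; tails keep every compound class reachable
    dmax <- cc - 1L
    dd <- sample(0:dmax, 1L,
                 prob = stats::dnorm(0:dmax, mean = 0.62 * cc,
                                     sd = 0.22 * cc) + 0.008)
    hh <- 2L * cc + 2L - 2L * dd
    if (hh < 1L || hh > 80L) next
    # oxygen draw biased low: lignin-derived polyphenol mixtures are
    # oxygen-poor, with number-averaged O/C below ~0.3
    oo <- stats::rbinom(1L, size = min(cc, 22L), prob = 0.22)
    if (hh / cc < 0.3 || hh / cc > 2.2 || oo / cc > 1) next
    f <- data.frame(c = cc, h = hh, o = oo, d = 0L, br = 0L)
    mass <- monoisotopic_mass(f)
    if (mass < mass_range[1] || mass > mass_range[2]) next
    cls <- compound_class(f)
    if (!is.null(class_mix)) {
      if (is.na(quota[cls]) || quota[cls] == 0 || filled[cls] >= quota[cls]) {
        next
      }
    }
    lab <- formula_label(f)
    if (lab %in% labels) next
    labels <- base::c(labels, lab)
    filled[cls] <- filled[cls] + 1L
    n_cooh <- min(oo %/% 2L, sample(0:2, 1L, prob = base::c(0.25, 0.5, 0.25)))
    n_carbonyl <- sample(0:min(2L, oo - 2L * n_cooh), 1L)
    n_exch <- min(hh, n_cooh + sample(1:4, 1L))
    picked[[length(picked) + 1L]] <- data.frame(
      f, formula = lab, mass = mass, class = cls,
      n_cooh = n_cooh, n_carbonyl = n_carbonyl,
      is_aromatic = aromaticity_index(f) > 0.5,
      n_exchangeable = n_exch, smiles = NA_character_
    )
  }
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  attr(out, "params") <- list(n = n, mass_range = mass_range,
                              class_mix = class_mix)
  class(out) <- base::c("ground_truth", "data.frame")
  out
}

# event count the labeling reaction produces for each ground-truth compound
reaction_event_counts <- function(truth, reaction) {
  switch(reaction,
    HD_EXCHANGE = truth$n_exchangeable,
    DEUTEROMETHYLATION = truth$n_cooh,
    REDUCTION = truth$n_carbonyl,
    BROMINATION = as.integer(truth$is_aromatic),
    stop("unknown labeling reaction: ", reaction)
  )
}

#' Simulate a labeled negative-mode spectrum of a ground-truth mixture
#'
#' Every compound contributes its \eqn{[M-H]^-} base peak; compounds with a
#' positive event count for the reaction additionally contribute member
#' peaks at `base + k * delta` for `k = 1..count`. Labeling efficiency
#' thins members as a consecutive prefix: each next member survives with
#' probability `efficiency`, and the series stops at the first loss (an
#' incompletely labeled molecule still carries all lighter labels).
#' Gaussian m/z jitter is applied per peak; decoy peaks are uniform over
#' the spectrum's m/z span; intensities are log-normal.
#'
#' @param truth A `ground_truth` table from [generate_mixture()].
#' @param reaction Reaction name, see [reactions()].
#' @param efficiency Per-member survival probability in \[0, 1\]; 0 yields
#'   base peaks only.
#' @param n_decoys Number of uniform random noise peaks.
#' @param mz_jitter_sd Gaussian m/z error SD in Th.
#' @param seed Random seed.
#' @param sample_id Sample identifier for the spectrum.
#' @param subset Optional integer/logical index: only these truth compounds
#'   receive labeling series (all still contribute base peaks).
#' @param metadata Extra spectrum metadata.
#' @return A `mass_spectrum`; attribute `planted` is a data frame
#'   (`formula`, `base_mz`, `k_planted`) of the series actually planted.
#' @export
simulate_label_spectrum <- function(truth, reaction = "HD_EXCHANGE",
                                    efficiency = 1, n_decoys = 0L,
                                    mz_jitter_sd = 0, seed = 1L,
                                    sample_id = "sim",
                                    subset = NULL, metadata = list()) {
  stopifnot(efficiency >= 0, efficiency <= 1, mz_jitter_sd >= 0)
  set.seed(seed)
  delta <- reaction_mass_shift(reaction)
  k_true <- reaction_event_counts(truth, reaction)
  if (!is.null(subset)) {
    sel <- logical(nrow(truth))
    sel[subset] <- TRUE
    k_true[!sel] <- 0L
  }
  base_ideal <- mz_from_formula(truth)
  mz <- numeric(0)
  intensity <- numeric(0)
  k_planted <- integer(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    base_int <- stats::rlnorm(1, meanlog = log(1e6), sdlog = 1)
    mz <- base::c(mz, base_ideal[i] + stats::rnorm(1, 0, mz_jitter_sd))
    intensity <- base::c(intensity, base_int)
    k_obs <- 0L
    if (k_true[i] > 0L && efficiency > 0) {
      surv <- stats::runif(k_true[i]) <= efficiency
      k_obs <- if (all(surv)) k_true[i] else which(!surv)[1L] - 1L
    }
    if (k_obs > 0L) {
      ks <- seq_len(k_obs)
      mz <- base::c(mz, base_ideal[i] + ks * delta +
                      stats::rnorm(k_obs, 0, mz_jitter_sd))
      intensity <- base::c(intensity,
                           base_int * stats::runif(k_obs, 0.2, 0.9))
    }
    k_planted[i] <- k_obs
  }
  if (n_decoys > 0L) {
    span <- range(mz)
    mz <- base::c(mz, stats::runif(n_decoys, span[1] - 5, span[2] + 5))
    intensity <- base::c(intensity,
                         stats::rlnorm(n_decoys, meanlog = log(1e5),
                                       sdlog = 1))
  }
  sp <- mass_spectrum(mz, intensity, sample_id = sample_id,
                      polarity = "negative", metadata = metadata)
  attr(sp, "planted") <- data.frame(
    formula = truth$formula, base_mz = base_ideal, k_planted = k_planted
  )
  sp
}

#' Simulate a complete tissue-extract sample set
#'
#' Builds the spectra a labeling dereplication experiment produces:
#' \itemize{
#'   \item control replicates: endogenous background formulae plus decoys,
#'     no labeling series;
#'   \item labeled-administration replicates per route: background plus the
#'     route's subset of ground-truth compounds carrying H/D-exchange
#'     series thinned by `efficiency` (in-vivo back-exchange);
#'   \item labeled-reference replicates: the labeled material itself, all
#'     compounds with full series (deep labeling of the pure material);
#'   \item parent-reference replicates: unlabeled material, base peaks
#'     only.
#' }
#' Route subsets share `route_overlap` of the compounds; the remainder is
#' split evenly, so the union always covers the whole mixture.
#'
#' @param truth A `ground_truth` table.
#' @param background_n Number of endogenous background formulae.
#' @param route_overlap Fraction of compounds administered by both routes.
#' @param n_replicates Replicate spectra per role.
#' @param n_decoys Decoy peaks per spectrum.
#' @param mz_jitter_sd Gaussian m/z error SD in Th.
#' @param efficiency Member survival probability in administration spectra.
#' @param seed Random seed.
#' @return A [sample_set()]; attribute `route_subsets` is a list of integer
#'   indices into `truth` per route.
#' @export
simulate_sample_set <- function(truth, background_n = 500L,
                                route_overlap = 1, n_replicates = 3L,
                                n_decoys = 5000L, mz_jitter_sd = 5e-5,
                                efficiency = 0.9, seed = 42L) {
  stopifnot(route_overlap >= 0, route_overlap <= 1, n_replicates >= 1L)
  set.seed(seed)
  sub_seed <- function() sample.int(2147483000L, 1L)
  bg_seed <- sub_seed()
  n_t <- nrow(truth)
  n_shared <- round(route_overlap * n_t)
  shuffled <- sample(n_t)
  shared <- shuffled[seq_len(n_shared)]
  rest <- setdiff(shuffled, shared)
  half <- length(rest) %/% 2L
  subsets <- list(
    parenteral = sort(base::c(shared, utils::head(rest, half))),
    oral = sort(base::c(shared, utils::tail(rest, length(rest) - half)))
  )
  spectra_seeds <- replicate(5L * n_replicates, sub_seed())
  # background formulae distinct from the planted truth
  bg <- generate_mixture(background_n + n_t, seed = bg_seed,
                         mass_range = range(truth$mass) + base::c(-20, 20))
  bg <- bg[!bg$formula %in% truth$formula, , drop = FALSE]
  bg <- bg[seq_len(min(background_n, nrow(bg))), , drop = FALSE]
  bg$n_exchangeable <- 0L  # endogenous: never labeled
  si <- 0L
  nxt <- function() {
    si <<- si + 1L
    spectra_seeds[si]
  }
  combined <- function(subset_idx) {
    tt <- truth[subset_idx, , drop = FALSE]
    rbind(tt, bg)
  }
  control <- lapply(seq_len(n_replicates), function(r) {
    simulate_label_spectrum(bg, "HD_EXCHANGE", efficiency = 0,
                            n_decoys = n_decoys, mz_jitter_sd = mz_jitter_sd,
                            seed = nxt(), sample_id = paste0("control_", r),
                            metadata = list(role = "control", replicate = r))
  })
  admin <- lapply(names(subsets), function(route) {
    lapply(seq_len(n_replicates), function(r) {
      tr <- combined(subsets[[route]])
      simulate_label_spectrum(
        tr, "HD_EXCHANGE", efficiency = efficiency,
        subset = seq_along(subsets[[route]]),
        n_decoys = n_decoys, mz_jitter_sd = mz_jitter_sd, seed = nxt(),
        sample_id = paste0(route, "_", r),
        metadata = list(role = "labeled_admin", route = route, replicate = r)
      )
    })
  })
  names(admin) <- names(subsets)
  labeled_ref <- lapply(seq_len(n_replicates), function(r) {
    simulate_label_spectrum(truth, "HD_EXCHANGE", efficiency = 1,
                            n_decoys = n_decoys, mz_jitter_sd = mz_jitter_sd,
                            seed = nxt(), sample_id = paste0("labeled_ref_", r),
                            metadata = list(role = "labeled_ref",
                                            replicate = r))
  })
  parent_ref <- lapply(seq_len(n_replicates), function(r) {
    simulate_label_spectrum(truth, "HD_EXCHANGE", efficiency = 0,
                            n_decoys = n_decoys, mz_jitter_sd = mz_jitter_sd,
                            seed = nxt(), sample_id = paste0("parent_ref_", r),
                            metadata = list(role = "parent_ref",
                                            replicate = r))
  })
  out <- sample_set(control, admin, labeled_ref, parent_ref)
  attr(out, "route_subsets") <- subsets
  out
}

#' Simulate chemical-tagging experiments on the parent material
#'
#' One spectrum per tagging reaction (deuteromethylation, reduction,
#' bromination, plus H/D exchange when requested) of the parent mixture
#' itself, with full series per compound: chemical derivatization of the
#' pure material is modeled as complete unless `efficiency` is lowered.
#'
#' @param truth A `ground_truth` table.
#' @param efficiency Member survival probability.
#' @param n_decoys Decoy peaks per spectrum.
#' @param mz_jitter_sd Gaussian m/z error SD in Th.
#' @param seed Random seed.
#' @param include_hd Also simulate the H/D-exchange experiment.
#' @return Named list of `mass_spectrum` objects keyed by reaction, ready
#'   for [aggregate_descriptors()].
#' @export
simulate_tag_experiments <- function(truth, efficiency = 1, n_decoys = 0L,
                                     mz_jitter_sd = 5e-5, seed = 7L,
                                     include_hd = TRUE) {
  set.seed(seed)
  rxns <- base::c("DEUTEROMETHYLATION", "REDUCTION", "BROMINATION",
                  if (include_hd) "HD_EXCHANGE")
  seeds <- sample.int(2147483000L, length(rxns))
  out <- lapply(seq_along(rxns), function(i) {
    simulate_label_spectrum(truth, rxns[i], efficiency = efficiency,
                            n_decoys = n_decoys,
                            mz_jitter_sd = mz_jitter_sd, seed = seeds[i],
                            sample_id = paste0("tag_", tolower(rxns[i])),
                            metadata = list(role = "tag", reaction = rxns[i]))
  })
  names(out) <- rxns
  out
}

# substituents (CHO only) used by the toy structure generator
.SUBSTITUENTS <- base::c("O", "C(=O)O", "C(C)=O", "C=O", "OC", "CO")

# cores with {i} substitution slots
.CORES <- list(
  base::c("c1ccc(", ")cc1"),
  base::c("c1cc(", ")cc(", ")c1"),
  base::c("c1ccc2cc(", ")ccc2c1"),
  base::c("C1CCC(", ")CC1"),
  base::c("CCC(", ")CC"),
  base::c("c1cc(", ")c(", ")c(", ")c1")
)

#' Generate a toy structure library
#'
#' Assembles random CHO SMILES strings from aromatic / aliphatic cores and
#' oxygen-bearing substituents (hydroxyl, carboxyl, acetyl, aldehyde,
#' methoxy, hydroxymethyl). Optionally injects syntactically invalid
#' strings and duplicates, for exercising structure standardization.
#'
#' @param n Number of strings.
#' @param seed Random seed.
#' @param p_invalid Fraction of deliberately invalid strings.
#' @param p_duplicate Fraction of repeated strings.
#' @return Character vector of SMILES strings (length `n`).
#' @export
generate_structures <- function(n, seed, p_invalid = 0, p_duplicate = 0) {
  set.seed(seed)
  make_one <- function() {
    core <- .CORES[[sample(length(.CORES), 1L)]]
    subs <- sample(.SUBSTITUENTS, length(core) - 1L, replace = TRUE)
    paste0(paste0(core[-length(core)], subs, collapse = ""),
           core[length(core)])
  }
  out <- vapply(seq_len(n), function(i) make_one(), character(1))
  n_dup <- round(p_duplicate * n)
  if (n_dup > 0L && n > 1L) {
    at <- sample(2:n, n_dup)
    out[at] <- out[sample(seq_len(n), n_dup, replace = TRUE)]
  }
  n_bad <- round(p_invalid * n)
  if (n_bad > 0L) {
    bad_pool <- base::c("not_a_smiles", "C1CC", "c1ccccc", "O=)C(")
    at <- sample(seq_len(n), n_bad)
    out[at] <- sample(bad_pool, n_bad, replace = TRUE)
  }
  out
}

#' Simulate solvent-fraction molecular profiles
#'
#' Emulates a gradient Soxhlet fractionation of the parent mixture: the
#' fraction inventory shifts from unsaturated-dominated (pure methanol)
#' toward aromatic and condensed-aromatic compounds as water content
#' rises, the formula count shrinks along the gradient, and the target
#' (ground-truth) compounds are most enriched in the pure-methanol
#' fraction.
#'
#' @param truth A `ground_truth` table — the target components.
#' @param seed Random seed.
#' @param n_background Size of the non-target formula pool.
#' @param fraction_ids Solvent labels, most to least methanol-rich.
#' @return Named list of [fraction_profile()] objects.
#' @export
simulate_fraction_profiles <- function(truth, seed = 11L,
                                       n_background = 1200L,
                                       fraction_ids = base::c(
                                         "100% CH3OH", "75% CH3OH",
                                         "50% CH3OH", "25% CH3OH")) {
  set.seed(seed)
  bg_seed <- sample.int(2147483000L, 1L)
  bg <- generate_mixture(n_background, seed = bg_seed)
  bg <- bg[!bg$formula %in% truth$formula, , drop = FALSE]
  pool <- rbind(truth, bg)
  pool_class <- pool$class
  is_target <- pool$formula %in% truth$formula
  n_frac <- length(fraction_ids)
  # class inclusion weights per fraction: unsaturated -> aromatic ->
  # condensed along the gradient
  wts <- list(
    UNSATURATED = seq(1.0, 0.35, length.out = n_frac),
    ALIPHATIC = seq(0.9, 0.3, length.out = n_frac),
    AROMATIC = seq(0.6, 1.0, length.out = n_frac),
    CONDENSED_AROMATIC = seq(0.25, 1.0, length.out = n_frac),
    LIPID_LIKE = rep(0.3, n_frac)
  )
  keep_frac <- seq(0.95, 0.6, length.out = n_frac)   # shrinking inventories
  # methanol most enriched: geometric decline of the target boost
  target_boost <- exp(seq(log(6), log(0.5), length.out = n_frac))
  target_keep <- seq(0.97, 0.55, length.out = n_frac)
  out <- lapply(seq_len(n_frac), function(f) {
    w <- vapply(pool_class, function(cl) wts[[cl]][f], numeric(1))
    keep <- stats::runif(nrow(pool)) < w * keep_frac[f]
    keep[is_target] <- stats::runif(sum(is_target)) < target_keep[f]
    int <- stats::rlnorm(sum(keep), meanlog = log(1e6), sdlog = 0.8)
    int <- int * ifelse(is_target[keep], target_boost[f], 1)
    fraction_profile(fraction_ids[f],
                     chem_formula(pool$c[keep], pool$h[keep], pool$o[keep]),
                     int)
  })
  names(out) <- fraction_ids
  out
}
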
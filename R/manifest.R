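#' Read a sample-set manifest
#'
#' A manifest is a YAML file mapping experiment roles to peak-list paths
#' (relative paths are resolved against the manifest's directory):
#'
#' ```yaml
#' control: [control_1.tsv, control_2.tsv]
#' labeled_admin:
#'   parenteral: [par_1.tsv, par_2.tsv]
#'   oral: [oral_1.tsv]
#' labeled_ref: [ref_1.tsv]
#' parent_ref: [parent_1.tsv]
#' tag_experiments:
#'   DEUTEROMETHYLATION: tag_dm.tsv
#'   REDUCTION: tag_red.tsv
#'   BROMINATION: tag_br.tsv
#' fractions:
#'   "100% CH3OH": frac_100.tsv
#'   "25% CH3OH": frac_25.tsv
#' ```
#'
#' @param path Manifest path.
#' @param dialect A [peaklist_dialect()] used for every peak list.
#' @return List with `sample_set` (a [sample_set()], when the spectra roles
#'   are present), `tag_experiments` (named list of spectra or NULL) and
#'   `fractions` (named list of spectra or NULL).
#' @export
read_manifest <- function(path, dialect = peaklist_dialect()) {
  man <- yaml::read_yaml(path)
  root <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(root, p))
  }
  load_many <- function(paths, role, extra = list()) {
    lapply(seq_along(paths), function(i) {
      read_peaklist(resolve(paths[[i]]), dialect = dialect,
                    metadata = base::c(list(role = role, replicate = i),
                                       extra))
    })
  }
  sset <- NULL
  if (!is.null(man$control) && !is.null(man$labeled_admin) &&
      !is.null(man$labeled_ref)) {
    admin <- lapply(names(man$labeled_admin), function(route) {
      load_many(man$labeled_admin[[route]], "labeled_admin",
                list(route = route))
    })
    names(admin) <- names(man$labeled_admin)
    sset <- sample_set(
      control = load_many(man$control, "control"),
      labeled_admin = admin,
      labeled_ref = load_many(man$labeled_ref, "labeled_ref"),
      parent_ref = if (!is.null(man$parent_ref)) {
        load_many(man$parent_ref, "parent_ref")
      }
    )
  }
  tags <- NULL
  if (!is.null(man$tag_experiments)) {
    tags <- lapply(names(man$tag_experiments), function(rxn) {
      read_peaklist(resolve(man$tag_experiments[[rxn]]), dialect = dialect,
                    metadata = list(role = "tag", reaction = rxn))
    })
    names(tags) <- names(man$tag_experiments)
  }
  fractions <- NULL
  if (!is.null(man$fractions)) {
    fractions <- lapply(names(man$fractions), function(fid) {
      read_peaklist(resolve(man$fractions[[fid]]), dialect = dialect,
                    metadata = list(role = "fraction", solvent = fid))
    })
    names(fractions) <- names(man$fractions)
  }
  list(sample_set = sset, tag_experiments = tags, fractions = fractions)
}

#' Write a simulated experiment to disk as peak lists plus manifest
#'
#' Materializes a [simulate_sample_set()] result (and optional tag and
#' fraction spectra) as TSV peak lists with a YAML manifest that
#' [read_manifest()] can load back.
#'
#' @param sset A [sample_set()].
#' @param dir Output directory (created if missing).
#' @param tag_experiments Optional named list of tag spectra.
#' @param fraction_spectra Optional named list of fraction spectra.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(sset, dir, tag_experiments = NULL,
                           fraction_spectra = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dump <- function(spectra, prefix) {
    vapply(seq_along(spectra), function(i) {
      fn <- paste0(prefix, "_", i, ".tsv")
      write_peaklist(spectra[[i]], file.path(dir, fn))
      fn
    }, character(1))
  }
  man <- list(
    control = as.list(dump(sset$control, "control")),
    labeled_admin = lapply(
      stats::setNames(names(sset$labeled_admin), names(sset$labeled_admin)),
      function(route) as.list(dump(sset$labeled_admin[[route]], route))
    ),
    labeled_ref = as.list(dump(sset$labeled_ref, "labeled_ref"))
  )
  if (!is.null(sset$parent_ref)) {
    man$parent_ref <- as.list(dump(sset$parent_ref, "parent_ref"))
  }
  if (!is.null(tag_experiments)) {
    man$tag_experiments <- lapply(
      stats::setNames(names(tag_experiments), names(tag_experiments)),
      function(rxn) {
        fn <- paste0("tag_", tolower(rxn), ".tsv")
        write_peaklist(tag_experiments[[rxn]], file.path(dir, fn))
        fn
      }
    )
  }
  if (!is.null(fraction_spectra)) {
    man$fractions <- lapply(
      stats::setNames(names(fraction_spectra), names(fraction_spectra)),
      function(fid) {
        fn <- paste0("fraction_", gsub("[^A-Za-z0-9]+", "_", fid), ".tsv")
        write_peaklist(fraction_spectra[[fid]], file.path(dir, fn))
        fn
      }
    )
  }
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(man, path)
  invisible(path)
}
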
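test_that("planted exogenous compounds are recovered with reference flags", {
  truth <- generate_mixture(20, seed = 5)
  sset <- simulate_sample_set(truth, background_n = 50, n_replicates = 2,
                              n_decoys = 0, mz_jitter_sd = 0,
                              efficiency = 1, seed = 8)
  recs <- detect_exogenous(sset, "parenteral")
  expect_setequal(recs$formula, truth$formula)
  expect_true(all(recs$in_labeled_ref))
  expect_true(all(recs$n_support == 2L))
  expect_true(all(vapply(recs$routes, identical, logical(1), "parenteral")))
})

test_that("labeled spectra identical to controls yield nothing", {
  truth <- generate_mixture(10, seed = 6)
  sset <- simulate_sample_set(truth, background_n = 30, n_replicates = 2,
                              n_decoys = 0, efficiency = 1, seed = 12)
  # substitute the control spectra in as the "labeled" ones
  sset$labeled_admin$parenteral <- sset$labeled_admin$oral <-
    sset$control
  recs <- detect_exogenous(sset, "parenteral")
  expect_equal(nrow(recs), 0L)
})

test_that("an unlabeled control peak does not veto a labeled series", {
  f <- parse_formula("C9H10O4")
  base_mz <- mz_from_formula(f)
  delta <- reaction_mass_shift("HD_EXCHANGE")
  labeled <- mass_spectrum(c(base_mz, base_mz + delta, base_mz + 2 * delta),
                           c(5, 3, 1))
  control <- mass_spectrum(base_mz, 5)  # same compound, no D series
  ref <- labeled
  sset <- sample_set(control = list(control, control),
                     labeled_admin = list(parenteral = list(labeled, labeled)),
                     labeled_ref = list(ref))
  recs <- detect_exogenous(sset, "parenteral")
  expect_equal(recs$formula, "C9H10O4")
  expect_equal(recs$n_exchangeable, 2L)
})

test_that("route merging follows inclusion-exclusion and is stable", {
  pool <- generate_mixture(60, seed = 14)
  a <- make_records(pool$formula[1:40], routes = "parenteral")
  b <- make_records(pool$formula[c(1:10, 41:60)], routes = "oral")
  merged <- merge_routes(list(a, b))
  expect_equal(nrow(merged), 60L)  # 40 + 30 - 10
  both <- vapply(merged$routes, length, integer(1))
  expect_equal(sum(both == 2L), 10L)

  # disjoint and identical unions
  expect_equal(nrow(merge_routes(list(make_records(pool$formula[1:3]),
                                      make_records(pool$formula[4:7],
                                                   routes = "oral")))), 7L)
  same <- make_records(pool$formula[1:5])
  expect_equal(nrow(merge_routes(list(same, same))), 5L)

  # idempotent and commutative in route order
  m1 <- merge_routes(list(a, b))
  m2 <- merge_routes(list(b, a))
  expect_equal(m1$formula, m2$formula)
  expect_equal(m1$routes, m2$routes)
  expect_equal(merge_routes(list(m1))$formula, m1$formula)
})

test_that("final filtration is conjunctive with logged attrition", {
  pool <- generate_mixture(10, seed = 15)
  recs <- make_records(pool$formula)
  recs$n_support[1:2] <- 1L        # fails min_support = 2
  recs$in_labeled_ref[3:4] <- FALSE
  out <- final_filter(recs)
  expect_equal(nrow(out), 6L)
  att <- attr(out, "attrition")
  expect_equal(att$n_removed[att$criterion == "min_support"], 2L)
  expect_equal(att$n_removed[att$criterion == "in_labeled_ref"], 2L)
  expect_true(all(out$formula %in% recs$formula))

  # adding a criterion never grows the output
  cfg_loose <- derep_config(min_support = 1L, require_labeled_ref = FALSE)
  expect_gte(nrow(final_filter(recs, cfg_loose)), nrow(out))
})

test_that("descriptor aggregation marks completeness per record", {
  truth <- generate_mixture(12, seed = 19)
  tags <- simulate_tag_experiments(truth, seed = 4)
  recs <- make_records(truth$formula)
  # drop the bromination experiment: aromaticity must come back unknown
  out_partial <- aggregate_descriptors(
    recs, tags[c("DEUTEROMETHYLATION", "REDUCTION")])
  expect_true(all(is.na(out_partial$is_aromatic)))
  expect_false(any(out_partial$descriptor_complete))

  out_full <- aggregate_descriptors(recs, tags)
  expect_true(all(out_full$descriptor_complete))
  m <- match(out_full$formula, truth$formula)
  expect_equal(out_full$n_cooh, truth$n_cooh[m])
  expect_equal(out_full$n_carbonyl, truth$n_carbonyl[m])
  expect_equal(out_full$is_aromatic, truth$is_aromatic[m])
})

test_that("component tables round-trip through CSV", {
  pool <- generate_mixture(5, seed = 21)
  recs <- make_records(pool$formula, routes = c("oral", "parenteral"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_components(recs, path)
  back <- read_components(path)
  expect_equal(back$formula, recs$formula)
  expect_equal(back$routes[[1]], c("oral", "parenteral"))
})

test_that("the pipeline report tracks per-stage counts", {
  truth <- generate_mixture(15, seed = 25)
  sset <- simulate_sample_set(truth, background_n = 40, n_replicates = 2,
                              n_decoys = 100, seed = 33)
  res <- run_dereplication(sset)
  expect_named(res$report, c("per_route", "merged_unique", "final",
                             "attrition"), ignore.order = TRUE)
  expect_gte(res$report$merged_unique, res$report$final)
  expect_true(all(res$components$formula %in% truth$formula))
})
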
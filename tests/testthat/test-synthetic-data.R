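test_that("mixture generation is reproducible and respects constraints", {
  t1 <- generate_mixture(10, seed = 1)
  t2 <- generate_mixture(10, seed = 1)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_false(identical(as.data.frame(t1),
                         as.data.frame(generate_mixture(10, seed = 2))))

  t3 <- generate_mixture(40, seed = 3, mass_range = c(100, 800))
  expect_true(all(t3$mass >= 100 & t3$mass <= 800))
  expect_false(anyDuplicated(t3$formula) > 0)
  # descriptor invariants hold
  expect_true(all(t3$n_cooh <= t3$o %/% 2))
  expect_true(all(t3$n_carbonyl <= t3$o - 2 * t3$n_cooh))
  expect_true(all(t3$n_exchangeable >= 1 & t3$n_exchangeable <= t3$h))

  arom <- generate_mixture(15, seed = 4,
                           class_mix = c(AROMATIC = 0.5,
                                         CONDENSED_AROMATIC = 0.5))
  expect_true(all(aromaticity_index(arom) > 0.5))
})

test_that("labeled spectra plant full series at efficiency one", {
  truth <- generate_mixture(12, seed = 9)
  sp <- simulate_label_spectrum(truth, "HD_EXCHANGE", efficiency = 1,
                                mz_jitter_sd = 0, seed = 10)
  planted <- attr(sp, "planted")
  expect_equal(planted$k_planted, truth$n_exchangeable)
  ser <- detect_series(sp, "HD_EXCHANGE", tol_mz = 3e-4)
  m <- match(round(planted$base_mz, 4), round(ser$base_mz, 4))
  expect_false(any(is.na(m)))
  expect_equal(ser$max_k[m], truth$n_exchangeable)

  # efficiency zero: bases only, nothing to detect
  sp0 <- simulate_label_spectrum(truth, "HD_EXCHANGE", efficiency = 0,
                                 seed = 10)
  expect_equal(n_peaks(sp0), nrow(truth))
  expect_equal(nrow(detect_series(sp0, "HD_EXCHANGE")), 0L)
})

test_that("m/z jitter keeps members within tolerance of ideal positions", {
  truth <- generate_mixture(50, seed = 13)
  delta <- reaction_mass_shift("HD_EXCHANGE")
  sp <- simulate_label_spectrum(truth, "HD_EXCHANGE", efficiency = 1,
                                mz_jitter_sd = 1e-4, seed = 14)
  planted <- attr(sp, "planted")
  deviations <- unlist(lapply(seq_len(nrow(planted)), function(i) {
    ks <- seq_len(planted$k_planted[i])
    ideal <- planted$base_mz[i] + ks * delta
    vapply(ideal, function(t) min(abs(sp$peaks$mz - t)), numeric(1))
  }))
  expect_gte(mean(deviations <= 3e-4), 0.99)
})

test_that("sample sets control route overlap as specified", {
  truth <- generate_mixture(50, seed = 16)
  ss_full <- simulate_sample_set(truth, background_n = 30, n_replicates = 2,
                                 n_decoys = 0, efficiency = 1,
                                 route_overlap = 1, seed = 17)
  subs <- attr(ss_full, "route_subsets")
  expect_equal(subs$parenteral, seq_len(50))
  expect_equal(subs$oral, seq_len(50))
  merged <- merge_routes(lapply(c("parenteral", "oral"), function(r) {
    detect_exogenous(ss_full, r)
  }))
  expect_equal(nrow(merged), 50L)

  ss_disj <- simulate_sample_set(truth, background_n = 10, n_replicates = 1,
                                 n_decoys = 0, efficiency = 1,
                                 route_overlap = 0, seed = 18)
  subs0 <- attr(ss_disj, "route_subsets")
  expect_length(intersect(subs0$parenteral, subs0$oral), 0)
  expect_setequal(union(subs0$parenteral, subs0$oral), seq_len(50))

  ss_half <- simulate_sample_set(truth, background_n = 10, n_replicates = 1,
                                 n_decoys = 0, route_overlap = 0.2, seed = 19)
  subs2 <- attr(ss_half, "route_subsets")
  expect_equal(length(intersect(subs2$parenteral, subs2$oral)), 10L)
  expect_equal(length(union(subs2$parenteral, subs2$oral)), 50L)
})

test_that("generators are bit-reproducible under a fixed seed", {
  truth <- generate_mixture(10, seed = 20)
  s1 <- simulate_label_spectrum(truth, "REDUCTION", efficiency = 0.8,
                                n_decoys = 50, mz_jitter_sd = 1e-4,
                                seed = 21)
  s2 <- simulate_label_spectrum(truth, "REDUCTION", efficiency = 0.8,
                                n_decoys = 50, mz_jitter_sd = 1e-4,
                                seed = 21)
  expect_identical(s1$peaks, s2$peaks)
  ss1 <- simulate_sample_set(truth, background_n = 15, n_replicates = 2,
                             n_decoys = 20, seed = 22)
  ss2 <- simulate_sample_set(truth, background_n = 15, n_replicates = 2,
                             n_decoys = 20, seed = 22)
  expect_identical(ss1$control[[1]]$peaks, ss2$control[[1]]$peaks)
  expect_identical(ss1$labeled_admin$oral[[2]]$peaks,
                   ss2$labeled_admin$oral[[2]]$peaks)
  expect_identical(generate_structures(50, seed = 23),
                   generate_structures(50, seed = 23))
})

test_that("descriptor ground truth survives the tagging simulation", {
  truth <- generate_mixture(50, seed = 42)
  tags <- simulate_tag_experiments(truth, seed = 7)
  recs <- make_records(truth$formula)
  out <- aggregate_descriptors(recs, tags)
  m <- match(out$formula, truth$formula)
  exact <- out$n_cooh == truth$n_cooh[m] &
    out$n_carbonyl == truth$n_carbonyl[m] &
    out$is_aromatic == truth$is_aromatic[m]
  expect_gte(mean(exact, na.rm = TRUE), 0.9)
})
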
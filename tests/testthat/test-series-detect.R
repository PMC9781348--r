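test_that("H/D chains are found with the documented base/member layout", {
  sp <- mass_spectrum(c(121.0295, 122.0358, 123.0421), c(3, 2, 1))
  ser <- detect_series(sp, "HD_EXCHANGE", tol_mz = 0.0003)
  expect_equal(nrow(ser), 1L)
  expect_equal(ser$base_mz, 121.0295)
  expect_equal(ser$max_k, 2L)
  expect_equal(ser$member_k[[1]], 0:2)

  # gap of 1.00700 is 0.00072 beyond the shift: no series
  sp2 <- mass_spectrum(c(100.0000, 101.0070), c(1, 1))
  expect_equal(nrow(detect_series(sp2, "HD_EXCHANGE", tol_mz = 0.0003)), 0L)

  expect_equal(nrow(detect_series(mass_spectrum(numeric(0), numeric(0)),
                                  "HD_EXCHANGE")), 0L)
})

test_that("detection equals the all-pairs brute-force chain builder", {
  delta <- reaction_mass_shift("HD_EXCHANGE")
  set.seed(23)
  for (case in 1:20) {
    n_base <- sample(3:12, 1)
    mz <- runif(n_base, 100, 500)
    # plant chains of random length, some overlapping
    for (b in sample(n_base, sample(2:n_base, 1))) {
      k <- sample(1:5, 1)
      mz <- c(mz, mz[b] + seq_len(k) * delta + runif(k, -2e-4, 2e-4))
    }
    mz <- c(mz, runif(30, 100, 500))  # decoys
    sp <- mass_spectrum(mz, rep(1, length(mz)))
    fast <- detect_series(sp, "HD_EXCHANGE", tol_mz = 3e-4, k_max = 8)
    slow <- brute_force_series(sp$peaks$mz, delta, 3e-4, 8)
    expect_equal(nrow(fast), length(slow))
    if (length(slow)) {
      expect_equal(fast$base_idx, vapply(slow, `[[`, integer(1), "base"))
      for (j in seq_along(slow)) {
        expect_equal(fast$member_idx[[j]], slow[[j]]$members)
      }
    }
  }
})

test_that("shrinking the tolerance never adds series", {
  set.seed(31)
  delta <- reaction_mass_shift("HD_EXCHANGE")
  mz <- c(runif(50, 100, 400))
  for (b in 1:10) mz <- c(mz, mz[b] + delta + runif(1, -4e-4, 4e-4))
  sp <- mass_spectrum(mz, rep(1, length(mz)))
  tols <- c(5e-4, 3e-4, 2e-4, 1e-4, 5e-5)
  counts <- vapply(tols, function(tol) {
    nrow(detect_series(sp, "HD_EXCHANGE", tol_mz = tol))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("chemistry rules prune infeasible series", {
  # base C7H6O2: one COOH possible at most, six exchangeable H at most
  f <- parse_formula("C7H6O2")
  base_mz <- mz_from_formula(f)
  mk_series <- function(reaction, max_k) {
    delta <- reaction_mass_shift(reaction)
    sp <- mass_spectrum(c(base_mz, base_mz + seq_len(max_k) * delta),
                        rep(1, max_k + 1))
    detect_series(sp, reaction, tol_mz = 3e-4)
  }
  asg <- assign_formulas(mass_spectrum(base_mz, 1))

  dm3 <- filter_series(mk_series("DEUTEROMETHYLATION", 3), asg)
  expect_equal(nrow(dm3), 0L)
  expect_equal(attr(dm3, "rejections")$rule, "max_k_infeasible")

  hd2 <- filter_series(mk_series("HD_EXCHANGE", 2), asg)
  expect_equal(nrow(hd2), 1L)
  expect_equal(hd2$formula, "C7H6O2")

  # a base with no assignment at all is rejected
  no_asg <- assign_formulas(mass_spectrum(500.0001, 1))
  hd_lost <- filter_series(mk_series("HD_EXCHANGE", 2), no_asg)
  expect_equal(nrow(hd_lost), 0L)
  expect_equal(attr(hd_lost, "rejections")$rule, "no_formula_assignment")
})

test_that("series lengths fold into functional-group descriptors", {
  f <- parse_formula("C9H8O5")
  fake <- function(max_k) data.frame(max_k = max_k, formula = "C9H8O5")
  d <- descriptors_from_series(f, list(
    DEUTEROMETHYLATION = fake(2), REDUCTION = fake(1), BROMINATION = fake(1)
  ))
  expect_equal(d$n_cooh, 2L)
  expect_equal(d$n_carbonyl, 1L)
  expect_true(d$is_aromatic)
  expect_true(d$complete)
  expect_true(is.na(d$n_exchangeable))  # H/D experiment not run

  # reduction run but silent: zero carbonyls, still complete with the rest
  d2 <- descriptors_from_series(f, list(
    DEUTEROMETHYLATION = fake(1), BROMINATION = fake(1)
  ), experiments_run = c("DEUTEROMETHYLATION", "REDUCTION", "BROMINATION"))
  expect_equal(d2$n_carbonyl, 0L)
  expect_true(d2$complete)

  # nothing run: everything unknown
  d3 <- descriptors_from_series(f, list(), experiments_run = character())
  expect_true(is.na(d3$n_cooh) && is.na(d3$n_carbonyl) &&
                is.na(d3$is_aromatic))
  expect_false(d3$complete)

  # mismatched base formula is a consistency error
  expect_error(
    descriptors_from_series(f, list(REDUCTION = data.frame(
      max_k = 1, formula = "C8H8O5"
    ))),
    "mismatch"
  )
})

test_that("series tables export base, formula and members", {
  sp <- mass_spectrum(c(121.029503, 122.035783), c(2, 1))
  ser <- detect_series(sp, "HD_EXCHANGE")
  fser <- filter_series(ser, assign_formulas(sp))
  path <- withr::local_tempfile(fileext = ".csv")
  write_series(fser, path)
  back <- read.csv(path)
  expect_equal(back$formula, "C7H6O2")
  expect_equal(back$max_k, 1L)
  expect_match(back$member_mzs, "121.029503;122.035783")
})
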
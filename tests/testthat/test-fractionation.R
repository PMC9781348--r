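test_that("number averages follow the (metric)n convention", {
  p <- fraction_profile("test", parse_formula(c("C6H6O", "C6H6O3")),
                        c(10, 10))
  expect_equal(number_average(p, "oc"), mean(c(1 / 6, 3 / 6)))
  expect_equal(number_average(p, "oc", weighting = "intensity"),
               number_average(p, "oc"))  # equal weights degenerate

  p1 <- fraction_profile("one", parse_formula("C7H6O2"), 5)
  expect_equal(number_average(p1, "hc"), 6 / 7)
  expect_equal(number_average(p1, "mass"), 122.0367794, tolerance = 1e-6)

  # intensity weighting responds to intensities, the number average not
  p2 <- fraction_profile("two", parse_formula(c("C6H6O", "C6H6O3")),
                         c(100, 1))
  expect_equal(number_average(p2, "oc"), mean(c(1 / 6, 3 / 6)))
  expect_gt(abs(number_average(p2, "oc", weighting = "intensity") -
                  number_average(p2, "oc")), 0.1)

  expect_error(
    number_average(fraction_profile("empty", parse_formula(character()),
                                    numeric(0)), "oc"),
    "empty"
  )
})

test_that("number averages ignore intensity rescaling", {
  set.seed(41)
  truth <- generate_mixture(30, seed = 44)
  p <- fraction_profile("a", truth, runif(30, 1, 100))
  p_scaled <- fraction_profile("a", truth, p$intensity * 1e4)
  for (m in c("oc", "hc", "ai", "mass")) {
    expect_equal(number_average(p, m), number_average(p_scaled, m))
  }
})

test_that("class distributions exclude lipids and renormalise", {
  p <- fraction_profile("x", parse_formula(c("C10H8", "C12H8O")), c(1, 3))
  d <- class_distribution(p)
  expect_equal(d$class, "CONDENSED_AROMATIC")
  expect_equal(d$count_share, 1)
  expect_equal(d$intensity_share, 1)

  p2 <- fraction_profile("y", parse_formula(c("C18H36O2", "C7H6O2")),
                         c(100, 1))
  d2 <- class_distribution(p2, exclude = "LIPID_LIKE")
  expect_false("LIPID_LIKE" %in% d2$class)
  expect_equal(sum(d2$count_share), 1)
  expect_equal(sum(d2$intensity_share), 1)

  expect_equal(nrow(class_distribution(
    fraction_profile("e", parse_formula(character()), numeric(0)))), 0L)
})

test_that("class shares sum to one over random profiles", {
  for (s in 1:5) {
    truth <- generate_mixture(40, seed = 100 + s)
    p <- fraction_profile("r", truth, stats::rlnorm(40, 10, 1))
    d <- class_distribution(p)
    expect_equal(sum(d$count_share), 1, tolerance = 1e-12)
    expect_equal(sum(d$intensity_share), 1, tolerance = 1e-12)
  }
})

test_that("enrichment scores are intensity shares of the target set", {
  p <- fraction_profile("z", parse_formula(c("C6H6O", "C7H6O2", "C10H8")),
                        c(0.5, 0.3, 0.2))
  expect_equal(enrichment_score(p, c("C6H6O", "C7H6O2")), 0.8)
  expect_equal(enrichment_score(p, p$formula), 1.0)
  expect_equal(enrichment_score(p, "C99H8O"), 0.0)
  expect_error(enrichment_score(
    fraction_profile("e", parse_formula(character()), numeric(0)), "C6H6O"),
    "empty")
})

test_that("enrichment is bounded and monotone in the target set", {
  set.seed(51)
  for (s in 1:10) {
    truth <- generate_mixture(25, seed = 200 + s)
    p <- fraction_profile("r", truth, stats::rlnorm(25, 8, 2))
    targets <- sample(truth$formula, sample(0:25, 1))
    sc <- enrichment_score(p, targets)
    expect_gte(sc, 0)
    expect_lte(sc, 1)
    extra <- setdiff(p$formula, targets)
    if (length(extra)) {
      expect_gte(enrichment_score(p, c(targets, extra[1])), sc)
    }
  }
})

test_that("fractions rank by enrichment with stable ties", {
  t1 <- parse_formula(c("C6H6O", "C7H6O2"))
  mk <- function(id, target_int, other_int) {
    fraction_profile(id, parse_formula(c("C6H6O", "C7H6O2", "C10H8")),
                     c(target_int / 2, target_int / 2, other_int))
  }
  profs <- list(mk("low", 1, 9), mk("high", 6, 4), mk("mid", 3, 7))
  ranked <- rank_fractions(profs, t1)
  expect_equal(names(attr(ranked, "scores")), c("high", "mid", "low"))
  expect_equal(unname(attr(ranked, "scores")), c(0.6, 0.3, 0.1))

  tied <- rank_fractions(list(mk("first", 2, 8), mk("second", 2, 8)), t1)
  expect_equal(names(attr(tied, "scores")), c("first", "second"))

  single <- rank_fractions(list(mk("only", 1, 1)), t1)
  expect_length(single, 1)
})

test_that("simulated fractionation shows the gradient and methanol enrichment", {
  truth <- generate_mixture(30, seed = 61)
  profs <- simulate_fraction_profiles(truth, seed = 62, n_background = 400)
  ranked <- rank_fractions(profs, truth$formula)
  expect_equal(attr(ranked[[1]], "fraction_id"), "100% CH3OH")
  # inventory shrinks along the gradient
  expect_gt(nrow(profs[["100% CH3OH"]]), nrow(profs[["25% CH3OH"]]))
  # condensed-aromatic share grows toward the water-rich fractions
  d100 <- class_distribution(profs[["100% CH3OH"]])
  d25 <- class_distribution(profs[["25% CH3OH"]])
  share <- function(d, cl) {
    if (cl %in% d$class) d$count_share[d$class == cl] else 0
  }
  expect_gt(share(d25, "CONDENSED_AROMATIC"), share(d100, "CONDENSED_AROMATIC"))
})

test_that("van Krevelen exports carry ratios and classes", {
  p <- fraction_profile("vk", parse_formula(c("C7H6O2", "C10H8", "C6H12O6")),
                        c(1, 2, 3))
  path <- withr::local_tempfile(fileext = ".csv")
  van_krevelen_export(p, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 3L)
  row <- back[back$formula == "C7H6O2", ]
  expect_equal(row$oc, 2 / 7, tolerance = 1e-4)
  expect_equal(row$hc, 6 / 7, tolerance = 1e-4)

  # empty profile: header-only file
  pe <- fraction_profile("e", parse_formula(character()), numeric(0))
  path2 <- withr::local_tempfile(fileext = ".csv")
  van_krevelen_export(pe, path2)
  expect_equal(nrow(read.csv(path2)), 0L)

  # plot artifact is produced on request
  path3 <- withr::local_tempfile(fileext = ".png")
  van_krevelen_export(p, path, plot_path = path3)
  expect_true(file.size(path3) > 0)
})
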
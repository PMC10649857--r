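rules <- decision_rules()

test_that("I-CVI is the top-box proportion", {
  expect_equal(compute_icvi(item_ratings(ratings_with(27, 30, 135), "q")), 0.9)
  expect_equal(compute_icvi(item_ratings(rep(5, 10), "q")), 1)
  expect_equal(compute_icvi(item_ratings(rep(2, 10), "q")), 0)
  # generalized top box
  loose <- decision_rules(top_box_min = 3)
  expect_equal(compute_icvi(item_ratings(c(3, 3, 1), "q"), loose), 2 / 3)
})

test_that("chance agreement matches the exact binomial point mass", {
  # independent oracle: stats::dbinom
  for (N in c(1, 5, 12, 30, 60)) {
    A <- 0:N
    expect_equal(chance_agreement(A, N), dbinom(A, N, 0.5), tolerance = 1e-14)
  }
  expect_equal(chance_agreement(0, 1), 0.5)
  expect_equal(chance_agreement(18, 30), choose(30, 18) / 2^30)
  # stable far beyond naive-factorial overflow
  expect_gt(chance_agreement(500, 1000), 0)
  expect_lt(chance_agreement(500, 1000), 0.03)
  expect_error(chance_agreement(5, 4), "0 <= A <= N")
  expect_error(chance_agreement(-1, 4), "0 <= A <= N")
})

test_that("chance agreement is symmetric and normalized", {
  set.seed(1)
  for (k in 1:20) {
    N <- sample(1:60, 1)
    A <- sample(0:N, 1)
    expect_equal(chance_agreement(A, N), chance_agreement(N - A, N))
  }
  for (N in 1:60) {
    expect_equal(sum(chance_agreement(0:N, N)), 1, tolerance = 1e-12)
  }
})

test_that("modified kappa corrects the CVI for chance and never exceeds it", {
  expect_equal(round_half_up(kappa_from_counts(18, 30)), 0.565)
  expect_equal(round_half_up(kappa_from_counts(17, 30)), 0.512)
  item <- item_ratings(ratings_with(18, 30, 103), "q")
  expect_equal(modified_kappa(item, rules), kappa_from_counts(18, 30))
  # kappa <= cvi everywhere, strictly when Pc > 0
  set.seed(2)
  for (k in 1:50) {
    N <- sample(1:200, 1)
    A <- sample(0:N, 1)
    expect_lt(kappa_from_counts(A, N), A / N + 1e-15)
  }
  # Pc -> 0 limit: kappa -> cvi
  expect_equal(kappa_from_counts(999, 1000), 999 / 1000, tolerance = 1e-6)
})

test_that("Aiken's V rescales the mean rating and is per-rating linear", {
  expect_equal(aiken_v(item_ratings(c(5, 5, 5, 4, 4), "q")), (4.6 - 1) / 4)
  expect_equal(aiken_v(item_ratings(rep(1, 8), "q")), 0)
  expect_equal(aiken_v(item_ratings(c(3, 4, 5), "q")), 0.75)
  set.seed(3)
  for (k in 1:10) {
    r <- sample(1:5, 20, replace = TRUE)
    item <- item_ratings(r, "q")
    expect_equal(aiken_v(item), mean((r - 1) / 4))
  }
})

test_that("score interval endpoints are the roots of the score test", {
  set.seed(4)
  for (k in 1:100) {
    v <- runif(1)
    n <- sample(2:80, 1)
    R <- sample(1:6, 1)
    z <- runif(1, 0.1, 3)
    ci <- aiken_ci(v, n, R, z)
    for (p in c(ci$lower, ci$upper)) {
      resid <- (v - p)^2 * n * R - z^2 * p * (1 - p)
      expect_lt(abs(resid), 1e-9)
    }
    expect_true(ci$lower >= 0 && ci$upper <= 1)
    expect_true(ci$lower <= v && v <= ci$upper)
  }
})

test_that("score interval collapses at z = 0 and narrows with the panel", {
  expect_equal(unlist(aiken_ci(0.73, 30, 4, z = 0)),
               c(lower = 0.73, upper = 0.73))
  for (v in c(0.2, 0.5, 0.9)) {
    widths <- sapply(c(5, 10, 20, 40, 80, 160), function(n) {
      ci <- aiken_ci(v, n)
      ci$upper - ci$lower
    })
    expect_true(all(diff(widths) < 0))
  }
})

test_that("the Wilson interval around CVI is the unit-range score interval", {
  expect_equal(cvi_wilson_ci(0.9, 30), aiken_ci(0.9, 30, scale_range = 1))
  expect_error(cvi_wilson_ci(1.2, 30), "\\[0, 1\\]")
})

test_that("comprehensibility bands follow the configured bounds", {
  expect_equal(comprehension_band(c(4.2, 3.7, 3.0)),
               c("high", "medium", "low"))
  # boundary: 4 is high, 3.5 is medium under the defaults
  expect_equal(comprehension_band(c(4, 3.5)), c("high", "medium"))
  # configurable boundary: strict 'above 4' reading
  strict <- decision_rules(comprehension_high = 4 + 1e-9)
  expect_equal(comprehension_band(4, strict), "medium")
  expect_error(comprehension_band(5.2), "outside scale")
})

test_that("evaluate_item bundles all indices from unrounded intermediates", {
  # A = 20 of 30 with mean 3.9
  rel <- item_ratings(ratings_with(20, 30, 117), "q8")
  out <- evaluate_item(rel, rules = rules)
  expect_equal(round_half_up(out$cvi), 0.667)
  expect_equal(round_half_up(out$kappa), 0.657)
  expect_equal(out$v, 0.725)
  expect_equal(out$mean_rating, 3.9)

  perfect <- evaluate_item(item_ratings(rep(5, 30), "q"))
  expect_equal(perfect[, c("cvi", "kappa", "v")],
               tibble::tibble(cvi = 1, kappa = 1, v = 1))

  single <- evaluate_item(item_ratings(4L, "q"))
  expect_equal(single$cvi, 1)
  expect_equal(single$v, 0.75)
  expect_equal(single$pc, 0.5)
  expect_equal(single$kappa, 1)

  with_comp <- evaluate_item(rel, item_ratings(rep(c(4L, 3L), 15), "q8"))
  expect_equal(with_comp$mean_comprehension, 3.5)
  expect_equal(with_comp$comprehension_band, "medium")
})

test_that("evaluate_items pairs dimensions and requires relevance", {
  tbl <- validate_ratings(dplyr::bind_rows(
    item_rows("a", c(5, 5, 4), c(4, 4, 4)),
    item_rows("b", c(2, 3, 3))))
  out <- evaluate_items(tbl)
  expect_equal(out$item_id, c("a", "b"))
  expect_equal(out$cvi, c(1, 0))
  expect_equal(out$comprehension_band, c("high", NA))

  comp_only <- validate_ratings(
    ratings_rows("c", c(4, 4), dimension = "comprehensibility"))
  expect_error(evaluate_items(comp_only), "no relevance ratings")
})
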
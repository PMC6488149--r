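test_that("two-sided Poisson p-values match the pmf-summation oracle", {
  # spot grid here (the acceptance suite runs the full grid)
  for (mu in c(0.5, 2, 5, 10)) {
    for (x in c(0, 1, 4, 5, 6, 20, 40)) {
      expect_equal(poisson_two_sided(x, T = 1, r = mu),
                   poisson_oracle(x, mu), tolerance = 1e-11,
                   label = sprintf("x=%d mu=%g", x, mu))
    }
  }
  # degenerate null and at-the-mode cases
  expect_equal(poisson_two_sided(0, T = 1, r = 0), 1)
  expect_equal(poisson_two_sided(5, T = 1, r = 5), 1)
  expect_error(poisson_two_sided(2.5, 1, 1), "integer")
  expect_error(poisson_two_sided(2, 0, 1), "T")
})

test_that("Poisson test agrees with the reference implementation", {
  set.seed(41)
  for (i in 1:100) {
    x <- rpois(1, 8)
    T <- runif(1, 0.5, 2e6)
    r <- runif(1, 1e-7, 20 / T)
    expect_equal(poisson_two_sided(x, T, r),
                 stats::poisson.test(x, T, r)$p.value, tolerance = 1e-12)
  }
})

test_that("expectation intervals bracket the stated mass and match a CDF scan", {
  scan_interval <- function(mu, alpha = 0.025) {
    lo <- 0
    while (ppois(lo, mu) <= alpha) lo <- lo + 1
    hi <- 0
    while (ppois(hi, mu) < 1 - alpha) hi <- hi + 1
    c(lo = lo, hi = hi)
  }
  for (mu in c(0.5, 1, 5, 20, 100, 1234.5)) {
    iv <- expectation_interval(T = 1, r = mu)
    expect_equal(iv, scan_interval(mu), label = sprintf("mu=%g", mu))
    # guaranteed coverage by construction
    expect_gte(ppois(iv["hi"], mu) - ppois(iv["lo"] - 1, mu), 0.95)
    expect_true(iv["lo"] <= mu && mu <= iv["hi"])
  }
  expect_equal(unname(expectation_interval(1, 0)), c(0, 0))
})

test_that("Fisher comparison equals full hypergeometric enumeration", {
  expect_equal(fisher_rate_comparison(list(events = 1, exposure = 2),
                                      list(events = 1, exposure = 2)), 1)
  cases <- list(c(10, 100, 2, 100), c(1, 9, 9, 1), c(0, 10, 5, 5),
                c(7, 3, 2, 8), c(25, 35, 12, 48))
  for (cs in cases) {
    mine <- fisher_rate_comparison(
      list(events = cs[1], exposure = cs[1] + cs[2]),
      list(events = cs[3], exposure = cs[3] + cs[4]))
    expect_equal(mine, fisher_oracle(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-10,
                 label = paste(cs, collapse = ","))
    # symmetric in group order
    swapped <- fisher_rate_comparison(
      list(events = cs[3], exposure = cs[3] + cs[4]),
      list(events = cs[1], exposure = cs[1] + cs[2]))
    expect_equal(mine, swapped, tolerance = 1e-12)
  }
  expect_error(fisher_rate_comparison(list(events = 5, exposure = 3),
                                      list(events = 1, exposure = 2)),
               "negative")
})

test_that("Fisher carrier mode tests carrier prevalence", {
  pb_a <- tibble::tibble(m = c(1, 0, 2, 0), l = rep(100, 4),
                         carrier = c(TRUE, FALSE, TRUE, FALSE))
  pb_b <- tibble::tibble(m = c(0, 0, 0, 1), l = rep(100, 4),
                         carrier = c(FALSE, FALSE, FALSE, TRUE))
  p_carr <- fisher_rate_comparison(pb_a, pb_b, mode = "carriers")
  expect_equal(p_carr, fisher_oracle(2, 2, 1, 3), tolerance = 1e-10)
  p_rate <- fisher_rate_comparison(pb_a, pb_b, mode = "events_vs_exposure")
  expect_equal(p_rate, fisher_oracle(3, 397, 1, 399), tolerance = 1e-10)
})

test_that("Mann-Whitney exact enumeration handles separation and ties", {
  # most extreme arrangement of C(6,3) = 20: two-sided p = 2/20
  expect_equal(mannwhitney_burden(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # identical multisets: p = 1
  expect_equal(mannwhitney_burden(c(0, 1, 1, 2), c(0, 1, 1, 2)), 1)
  # shift invariance of a rank statistic
  set.seed(42)
  a <- rpois(6, 2); b <- rpois(7, 3)
  expect_equal(mannwhitney_burden(a, b), mannwhitney_burden(a + 10, b + 10))
  # agrees with permutation enumeration on tied count data
  for (i in 1:10) {
    a <- rpois(sample(3:8, 1), 2)
    b <- rpois(sample(3:8, 1), 3)
    expect_equal(mannwhitney_burden(a, b), mw_oracle(a, b),
                 label = sprintf("case %d", i))
  }
  # matches the reference exact test when there are no ties
  for (i in 1:10) {
    a <- sample(1000, 7); b <- sample(2000, 6)
    expect_equal(mannwhitney_burden(a, b),
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney large-sample path uses tie-corrected normal variance", {
  set.seed(43)
  for (i in 1:20) {
    a <- rpois(30, 3); b <- rpois(25, 4)
    expect_equal(mannwhitney_burden(a, b),
                 stats::wilcox.test(a, b, exact = FALSE,
                                    correct = FALSE)$p.value,
                 tolerance = 1e-10)
  }
  # all values identical: no information, p = 1
  expect_equal(mannwhitney_burden(rep(2, 20), rep(2, 25)), 1)
  expect_error(mannwhitney_burden(numeric(0), 1:3), "empty")
})

test_that("lambda is the pooled ratio of events to callable positions", {
  expect_equal(estimate_lambda(10, 1e6), 1e-5)
  expect_equal(estimate_lambda(c(5, 5), c(1e6, 1e6)), 5e-6)
  # pooled, not mean of per-sample ratios
  M <- c(10, 1); L <- c(1e6, 2e5)
  expect_equal(estimate_lambda(M, L), 11 / 1.2e6)
  expect_false(isTRUE(all.equal(estimate_lambda(M, L), mean(M / L))))
  expect_equal(estimate_lambda(c(0, 0), c(1e6, 1e6)), 0)
  expect_error(estimate_lambda(c(1, 2), c(0, 0)), "zero")
})
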
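make_pb <- function() {
  events <- tibble::tibble(
    sample_id = c("s1", "s1", "s2", "s3", "s4"),
    variant_id = paste0("v", 1:5),
    chrom = "chr1",
    pos = c(15, 500, 25, 600, 35), # 0-based 14,499,24,599,34
    depth = 30)
  exposure <- tidyr::expand_grid(sample_id = paste0("s", 1:4),
                                 region = c("exome", "panel"))
  exposure$callable_length <- ifelse(exposure$region == "exome", 1000, 40)
  populations <- tibble::tibble(sample_id = paste0("s", 1:4),
                                population = c("A", "A", "B", "B"))
  panel <- region_set("chr1", 10, 50)
  list(events = events, exposure = exposure, populations = populations,
       panel = panel)
}

test_that("per-sample burden records assemble events against exposures", {
  fx <- make_pb()
  pb <- population_burden(fx$events, fx$exposure, fx$populations, fx$panel)
  expect_equal(pb$sample_id, paste0("s", 1:4))
  expect_equal(pb$M, c(2, 1, 1, 1))   # all events count exome-wide
  expect_equal(pb$m, c(1, 1, 0, 1))   # only panel positions count in m
  expect_equal(pb$L, rep(1000, 4))
  expect_equal(pb$l, rep(40, 4))
  expect_equal(pb$carrier, c(TRUE, TRUE, FALSE, TRUE))
  # unassigned samples are rejected
  expect_error(
    population_burden(fx$events, fx$exposure,
                      fx$populations[1:2, ], fx$panel),
    "no population assignment")
})

test_that("burden tests reproduce hand-computed aggregates and p-values", {
  fx <- make_pb()
  pb <- population_burden(fx$events, fx$exposure, fx$populations, fx$panel)
  fit <- suppressWarnings(burden_test(pb, fisher_reference = "A"))
  td <- tidy(fit)
  a <- td[td$population == "A", ]
  expect_equal(a$lambda_hat, 3 / 2000)
  expect_equal(a$T, 80)
  expect_equal(a$x_obs, 2)
  expect_equal(a$expected, 3 / 2000 * 80)
  expect_equal(a$p_poisson,
               stats::poisson.test(2, 80, 3 / 2000)$p.value)
  expect_equal(unname(c(a$interval_lo, a$interval_hi)),
               unname(expectation_interval(80, 3 / 2000)))
  expect_equal(a$p_poisson_bonferroni, min(1, 2 * a$p_poisson))
  # pairwise rows exist for the non-reference population only
  expect_setequal(fit$pairwise$population, "B")
  expect_setequal(fit$pairwise$test,
                  c("fisher_events_vs_exposure", "fisher_carriers",
                    "mannwhitney_exome"))
  expect_warning(burden_test(pb), "fewer than")
  g <- glance(fit)
  expect_equal(g$n_samples, 4)
  expect_equal(g$total_panel_events, 3)
})

test_that("pooling preserves rates and gains power with exposure", {
  fx <- make_pb()
  pb <- population_burden(fx$events, fx$exposure, fx$populations, fx$panel)
  # two identical cohorts: pooled lambda equals the single-cohort lambda
  meta <- suppressWarnings(meta_pooled(list(c1 = pb, c2 = pb),
                                       min_samples = 1))
  td1 <- suppressWarnings(tidy(burden_test(pb, min_samples = 1)))
  tdm <- tidy(meta$meta)
  expect_equal(tdm$lambda_hat, td1$lambda_hat)
  expect_equal(tdm$x_obs, 2 * td1$x_obs)
  expect_equal(tdm$T, 2 * td1$T)
  # doubling (x, T) at a fixed rate sharpens the p-value when x/T > lambda
  p1 <- poisson_two_sided(12, 1000, 0.005)
  p2 <- poisson_two_sided(24, 2000, 0.005)
  expect_lt(p2, p1)
  # a single cohort cannot be meta-analyzed
  expect_error(meta_pooled(list(pb)), ">= 2 cohorts")
})

test_that("populations present in a single cohort are excluded with warning", {
  fx <- make_pb()
  pb <- population_burden(fx$events, fx$exposure, fx$populations, fx$panel)
  pb_b <- pb[pb$population == "B", ]
  class(pb_b) <- class(pb)
  expect_warning(
    meta <- meta_pooled(list(c1 = pb, c2 = pb_b), min_samples = 1),
    "only one cohort")
  expect_equal(tidy(meta$meta)$population, "B")
})

test_that("results tables round-trip at full precision", {
  fx <- make_pb()
  pb <- population_burden(fx$events, fx$exposure, fx$populations, fx$panel)
  fit <- suppressWarnings(burden_test(pb, fisher_reference = "A"))
  path <- tempfile(fileext = ".tsv")
  res <- write_results(fit, path)
  back <- read_results(path)
  expect_equal(nrow(back), nrow(res))
  for (col in c("lambda_hat", "observed", "expected", "p_value")) {
    expect_equal(signif(back[[col]], 12), signif(res[[col]], 12))
  }
  # refuse to write an empty collection
  empty_fit <- fit
  empty_fit$by_population <- fit$by_population[0, ]
  expect_error(write_results(empty_fit, path), "empty")
})
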
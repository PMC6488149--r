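#' Assemble per-sample burden records by population
#'
#' Joins filtered mutation events, per-sample callable exposures, and
#' population assignments into the per-sample table the burden tests
#' consume: `M` (exome-wide truncating events), `L` (exome callable
#' positions), `m` (events inside the gene panel), `l` (panel callable
#' positions), and the carrier flag (`m >= 1`).
#'
#' @param events Event tibble from [run_filter_cascade()] (`$events`).
#' @param exposure Exposure tibble from [build_exposure_table()] with
#'   regions named `"exome"` and `"panel"`.
#' @param populations Tibble `sample_id`, `population`. Every exposed
#'   sample must be assigned.
#' @param panel `region_set` of the gene panel (pre-intersected with the
#'   capture region), used to flag which events are panel events.
#' @return A `population_burden` tibble: `population`, `sample_id`, `M`,
#'   `L`, `m`, `l`, `carrier`. Samples with no events get zero counts.
#' @export
population_burden <- function(events, exposure, populations, panel) {
  stopifnot(all(c("sample_id", "population") %in% names(populations)))
  wide <- tidyr::pivot_wider(exposure, names_from = "region",
                             values_from = "callable_length")
  if (!all(c("exome", "panel") %in% names(wide))) {
    abort("exposure table must contain regions 'exome' and 'panel'")
  }
  unassigned <- setdiff(wide$sample_id, populations$sample_id)
  if (length(unassigned) > 0) {
    abort(sprintf("sample(s) with no population assignment: %s",
                  paste(unassigned, collapse = ", ")))
  }
  if (nrow(events) > 0) {
    events$in_panel <- region_member(events$chrom, events$pos - 1, panel,
                                     check_contigs = FALSE)
    per_sample <- events |>
      group_by(.data$sample_id) |>
      summarise(M = dplyr::n(), m = sum(.data$in_panel), .groups = "drop")
  } else {
    per_sample <- tibble(sample_id = character(), M = integer(),
                         m = integer())
  }
  out <- wide |>
    left_join(per_sample, by = "sample_id") |>
    mutate(M = ifelse(is.na(.data$M), 0L, .data$M),
           m = ifelse(is.na(.data$m), 0L, .data$m),
           carrier = .data$m >= 1) |>
    inner_join(populations[, c("sample_id", "population")],
               by = "sample_id") |>
    select("population", "sample_id", "M", L = "exome", "m", l = "panel",
           "carrier") |>
    arrange(.data$population, .data$sample_id)
  class(out) <- c("population_burden", class(tibble()))
  out
}

#' Panel enrichment and between-group burden tests
#'
#' For each population: estimates the background rate
#' `lambda = sum(M) / sum(L)` exome-wide, forms the expected panel count
#' `lambda * T` with `T = sum(l)`, and applies the exact two-sided Poisson
#' test to the observed panel count `x = sum(m)` ([poisson_two_sided()]),
#' with the central expectation interval ([expectation_interval()]).
#' Pairwise contrasts against configurable reference populations are
#' added: Fisher exact on event rates and on carrier prevalence
#' ([fisher_rate_comparison()]), and Mann-Whitney on per-sample exome-wide
#' counts ([mannwhitney_burden()]). Unadjusted p-values are reported; a
#' Bonferroni column (across populations) is included for transparency
#' only.
#'
#' @param pb A `population_burden` tibble.
#' @param level Coverage level of the expectation interval.
#' @param fisher_reference Population used as reference for the Fisher
#'   contrasts (default: the largest population).
#' @param mw_reference Population used as reference for the Mann-Whitney
#'   exome-wide contrast (default: same as `fisher_reference`).
#' @param fisher_mode 2x2 construction for the headline Fisher contrast;
#'   both modes are reported side by side regardless.
#' @param min_samples Populations smaller than this trigger a
#'   small-sample warning (default 5).
#' @return A `burden_fit` object; see [tidy.burden_fit()].
#' @export
burden_test <- function(pb, level = 0.95,
                        fisher_reference = NULL, mw_reference = NULL,
                        fisher_mode = c("events_vs_exposure", "carriers"),
                        min_samples = 5) {
  fisher_mode <- match.arg(fisher_mode)
  stopifnot(inherits(pb, "data.frame"), nrow(pb) > 0)
  sizes <- pb |> count(.data$population, name = "n")
  small <- sizes$population[sizes$n < min_samples]
  if (length(small) > 0) {
    warn(sprintf("population(s) with fewer than %d samples: %s; estimates may be unstable",
                 min_samples, paste(small, collapse = ", ")))
  }
  if (is.null(fisher_reference)) {
    fisher_reference <- sizes$population[which.max(sizes$n)]
  }
  if (is.null(mw_reference)) mw_reference <- fisher_reference

  by_pop <- pb |>
    group_by(.data$population) |>
    summarise(n = dplyr::n(),
              M_sum = sum(.data$M), L_sum = sum(.data$L),
              x_obs = sum(.data$m), T = sum(.data$l),
              carriers = sum(.data$carrier), .groups = "drop") |>
    mutate(lambda_hat = .data$M_sum / .data$L_sum,
           expected = .data$lambda_hat * .data$T,
           carrier_pct = 100 * .data$carriers / .data$n)
  iv <- t(vapply(seq_len(nrow(by_pop)), function(i) {
    expectation_interval(by_pop$T[i], by_pop$lambda_hat[i], level)
  }, numeric(2)))
  by_pop$interval_lo <- iv[, 1]
  by_pop$interval_hi <- iv[, 2]
  by_pop$p_poisson <- vapply(seq_len(nrow(by_pop)), function(i) {
    poisson_two_sided(by_pop$x_obs[i], by_pop$T[i], by_pop$lambda_hat[i])
  }, numeric(1))
  by_pop$p_poisson_bonferroni <- pmin(1, by_pop$p_poisson * nrow(by_pop))

  split_pb <- split(as_tibble(pb), pb$population)
  pairwise <- bind_rows(lapply(setdiff(names(split_pb), character(0)),
    function(pop) {
      rows <- list()
      if (pop != fisher_reference && fisher_reference %in% names(split_pb)) {
        ref <- split_pb[[fisher_reference]]
        rows <- c(rows, list(
          tibble(population = pop, reference = fisher_reference,
                 test = "fisher_events_vs_exposure",
                 p_value = fisher_rate_comparison(split_pb[[pop]], ref,
                                                  "events_vs_exposure")),
          tibble(population = pop, reference = fisher_reference,
                 test = "fisher_carriers",
                 p_value = fisher_rate_comparison(split_pb[[pop]], ref,
                                                  "carriers"))))
      }
      if (pop != mw_reference && mw_reference %in% names(split_pb)) {
        rows <- c(rows, list(
          tibble(population = pop, reference = mw_reference,
                 test = "mannwhitney_exome",
                 p_value = mannwhitney_burden(split_pb[[pop]]$M,
                                              split_pb[[mw_reference]]$M))))
      }
      bind_rows(rows)
    }))

  structure(list(by_population = by_pop, pairwise = pairwise,
                 params = list(level = level,
                               fisher_reference = fisher_reference,
                               mw_reference = mw_reference,
                               fisher_mode = fisher_mode)),
            class = "burden_fit")
}

#' @export
print.burden_fit <- function(x, ...) {
  cat("<burden_fit>\n")
  print(x$by_population)
  if (nrow(x$pairwise) > 0) {
    cat(sprintf("pairwise contrasts vs '%s' (Fisher) / '%s' (Mann-Whitney):\n",
                x$params$fisher_reference, x$params$mw_reference))
    print(x$pairwise)
  }
  invisible(x)
}

#' Tidy a burden fit
#'
#' @param x A `burden_fit`.
#' @param ... Unused.
#' @return `tidy()`: per-population tibble with aggregates (`M_sum`,
#'   `L_sum`, `x_obs`, `T`), `lambda_hat`, `expected`, the expectation
#'   interval, carrier prevalence and p-values. `glance()`: one-row
#'   summary.
#' @method tidy burden_fit
#' @export
tidy.burden_fit <- function(x, ...) x$by_population

#' @rdname tidy.burden_fit
#' @method glance burden_fit
#' @export
glance.burden_fit <- function(x, ...) {
  tibble(n_populations = nrow(x$by_population),
         n_samples = sum(x$by_population$n),
         total_exome_events = sum(x$by_population$M_sum),
         total_panel_events = sum(x$by_population$x_obs),
         min_p_poisson = min(x$by_population$p_poisson))
}

#' Pooled meta-analysis across cohorts
#'
#' Pools per-sample counts and exposures across cohorts population by
#' population (`sum(m)`, `sum(l)`, `sum(M)`, `sum(L)`), then applies the
#' same single-cohort tests to the pooled aggregates — the exact tests are
#' preserved under pooling of count/exposure pairs. Populations present in
#' only one cohort are excluded with a warning. Cohort provenance is
#' retained in the result.
#'
#' @param pbs Named list (>= 2) of `population_burden` tibbles, one per
#'   cohort.
#' @param ... Passed to [burden_test()].
#' @return A `burden_meta` list: `meta` (pooled `burden_fit`),
#'   `cohort_fits` (per-cohort `burden_fit`s), `pooled_pb` (pooled
#'   per-sample table with a `cohort` column).
#' @export
meta_pooled <- function(pbs, ...) {
  stopifnot(is.list(pbs), length(pbs) >= 1)
  if (length(pbs) == 1) {
    abort("meta-analysis needs >= 2 cohorts; use burden_test() for one")
  }
  nm <- names(pbs) %||% paste0("cohort", seq_along(pbs))
  nm[!nzchar(nm)] <- paste0("cohort", which(!nzchar(nm)))
  nm <- make.unique(nm, sep = "_")
  tagged <- purrr::map2(pbs, nm, function(pb, id) {
    mutate(as_tibble(pb), cohort = id,
           sample_id = paste(id, .data$sample_id, sep = ":"))
  })
  pop_cohorts <- bind_rows(tagged) |>
    distinct(.data$population, .data$cohort) |>
    count(.data$population, name = "n_cohorts")
  shared <- pop_cohorts$population[pop_cohorts$n_cohorts >= 2]
  if (length(shared) == 0) abort("no population shared across cohorts")
  dropped <- setdiff(pop_cohorts$population, shared)
  if (length(dropped) > 0) {
    warn(sprintf("population(s) present in only one cohort excluded from pooling: %s",
                 paste(dropped, collapse = ", ")))
  }
  pooled <- bind_rows(tagged) |> filter(.data$population %in% shared)
  class(pooled) <- c("population_burden", class(tibble()))
  cohort_fits <- lapply(pbs, function(pb) suppressWarnings(burden_test(pb, ...)))
  names(cohort_fits) <- nm
  structure(list(meta = burden_test(pooled, ...),
                 cohort_fits = cohort_fits,
                 pooled_pb = pooled),
            class = "burden_meta")
}

#' @export
print.burden_meta <- function(x, ...) {
  cat(sprintf("<burden_meta> pooled over %d cohorts (%s)\n",
              length(x$cohort_fits),
              paste(names(x$cohort_fits), collapse = ", ")))
  print(x$meta)
  invisible(x)
}

#' Write burden results as a round-trippable TSV
#'
#' One row per (population, region, test): the Poisson enrichment test in
#' the panel region plus the pairwise contrasts. Deterministic column
#' order; numeric values survive a write/read round trip at full
#' precision.
#'
#' @param fit A `burden_fit`.
#' @param path Output path.
#' @param region Region label recorded in the table (default `"panel"`).
#' @return The results tibble, invisibly.
#' @export
write_results <- function(fit, path, region = "panel") {
  stopifnot(inherits(fit, "burden_fit"))
  bp <- fit$by_population
  if (nrow(bp) == 0) abort("empty result collection")
  pois <- tibble(population = bp$population, region = region,
                 test = "poisson_enrichment", reference = NA_character_,
                 lambda_hat = bp$lambda_hat, observed = bp$x_obs,
                 expected = bp$expected,
                 interval_lo = bp$interval_lo, interval_hi = bp$interval_hi,
                 p_value = bp$p_poisson)
  pw <- fit$pairwise
  if (nrow(pw) > 0) {
    pw <- tibble(population = pw$population, region = region,
                 test = pw$test, reference = pw$reference,
                 lambda_hat = NA_real_, observed = NA_real_,
                 expected = NA_real_, interval_lo = NA_real_,
                 interval_hi = NA_real_, p_value = pw$p_value)
  }
  res <- bind_rows(pois, pw) |>
    arrange(.data$population, .data$test)
  write_tsv(res, path)
  invisible(res)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  read_tsv(path, col_types = cols(
    population = col_character(), region = col_character(),
    test = col_character(), reference = col_character(),
    lambda_hat = col_double(), observed = col_double(),
    expected = col_double(), interval_lo = col_double(),
    interval_hi = col_double(), p_value = col_double()))
}
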
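#' Run configuration for an end-to-end burden analysis
#'
#' Bundles the input paths, population assignments, filter settings and
#' analysis modes for one cohort. Serializable to/from YAML
#' ([read_run_config()]).
#'
#' @param cohort Cohort name (used in outputs and meta-analysis).
#' @param vcf Path to the annotated VCF.
#' @param coverage Named character vector of per-sample coverage BEDs
#'   (names = sample ids), or a directory of `<sample_id>.bed` files.
#' @param capture,panel Paths to the capture-region and panel BEDs.
#' @param masks Named character vector of mask BED paths (defaults expect
#'   `tandem_repeat` and `segdup`).
#' @param ccds Optional CCDS BED path.
#' @param populations Path to a TSV with columns `sample_id`,
#'   `population`.
#' @param filter A [filter_config()].
#' @param ccds_restrict Restrict analysis to CCDS (cross-cohort
#'   harmonization mode); requires `ccds`.
#' @param fisher_mode,fisher_reference,mw_reference Passed to
#'   [burden_test()].
#' @param out_dir Output directory for the result bundle.
#' @param key_map A [vcf_key_map()].
#' @param min_samples Small-population warning threshold.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort, vcf, coverage, capture, panel,
                       masks = NULL, ccds = NULL, populations,
                       filter = filter_config(), ccds_restrict = FALSE,
                       fisher_mode = "events_vs_exposure",
                       fisher_reference = NULL, mw_reference = NULL,
                       out_dir = NULL, key_map = vcf_key_map(),
                       min_samples = 5) {
  if (length(coverage) == 1 && dir.exists(coverage)) {
    files <- list.files(coverage, pattern = "\\.bed$", full.names = TRUE)
    coverage <- setNames(files, tools::file_path_sans_ext(basename(files)))
  }
  cfg <- structure(list(cohort = cohort, vcf = vcf, coverage = coverage,
                        capture = capture, panel = panel, masks = masks,
                        ccds = ccds, populations = populations,
                        filter = filter, ccds_restrict = ccds_restrict,
                        fisher_mode = fisher_mode,
                        fisher_reference = fisher_reference,
                        mw_reference = mw_reference, out_dir = out_dir,
                        key_map = key_map, min_samples = min_samples),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  for (p in c(cfg$vcf, cfg$capture, cfg$panel, cfg$populations,
              unname(cfg$masks), cfg$ccds, unname(cfg$coverage))) {
    if (!file.exists(p)) abort(sprintf("input path does not exist: %s", p))
  }
  if (cfg$ccds_restrict && is.null(cfg$ccds)) {
    abort("ccds_restrict = TRUE requires a ccds BED")
  }
  missing_masks <- setdiff(cfg$filter$masks, names(cfg$masks))
  if (length(missing_masks) > 0) {
    abort(sprintf("filter masks with no BED supplied: %s",
                  paste(missing_masks, collapse = ", ")))
  }
  invisible(cfg)
}

#' @rdname run_config
#' @param path YAML file with the fields of `run_config()` (filter
#'   thresholds under a `filter:` block).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    out <- ifelse(grepl("^/", p), p, file.path(base, p))
    setNames(out, names(p))
  }
  filt <- do.call(filter_config, y$filter %||% list())
  run_config(cohort = y$cohort %||% "cohort",
             vcf = resolve(y$vcf),
             coverage = resolve(unlist(y$coverage)),
             capture = resolve(y$capture),
             panel = resolve(y$panel),
             masks = resolve(unlist(y$masks)),
             ccds = resolve(y$ccds),
             populations = resolve(y$populations),
             filter = filt,
             ccds_restrict = isTRUE(y$ccds_restrict),
             fisher_mode = y$fisher_mode %||% "events_vs_exposure",
             fisher_reference = y$fisher_reference,
             mw_reference = y$mw_reference,
             out_dir = if (is.null(y$out_dir)) NULL else resolve(y$out_dir),
             min_samples = y$min_samples %||% 5)
}

#' Run the full burden pipeline for one cohort
#'
#' filter -> exposure -> burden -> report. Reads all inputs, validates
#' population assignments before any computation, runs the filter
#' cascade, builds the exposure table, assembles per-sample burden
#' records, and applies the burden tests. When `out_dir` is set, writes a
#' figure-ready bundle: the per-filter report, per-variant dispositions,
#' exposure table, per-sample exome-wide counts, the per-population panel
#' event/carrier summary, the observed-vs-expected table with expectation
#' intervals, the results TSV, and a JSON manifest of thresholds; partial
#' outputs are removed on failure.
#'
#' @param cfg A [run_config()].
#' @return A `burden_run` list: `filter` (filter_result), `exposure`,
#'   `pb` (population_burden), `fit` (burden_fit), `tables` (the
#'   figure-ready tibbles), `regions`, `config`.
#' @export
run_full <- function(cfg) {
  validate_run_config(cfg)
  regions <- list(capture = read_bed(cfg$capture, "capture"))
  panel_rs <- read_bed(cfg$panel, "panel")
  for (m in names(cfg$masks)) regions[[m]] <- read_bed(cfg$masks[[m]], m)
  if (!is.null(cfg$ccds)) regions$ccds <- read_bed(cfg$ccds, "ccds")

  pops <- read_tsv(cfg$populations,
                   col_types = cols(sample_id = col_character(),
                                    population = col_character()))
  variants <- read_vcf(cfg$vcf, key_map = cfg$key_map)
  vcf_samples <- attr(variants, "samples") %||% character(0)
  unassigned <- setdiff(vcf_samples, pops$sample_id)
  if (length(unassigned) > 0) {
    abort(sprintf("VCF sample(s) missing from the population table: %s",
                  paste(unassigned, collapse = ", ")))
  }

  filt_cfg <- cfg$filter
  if (cfg$ccds_restrict) {
    filt_cfg$restrict_to <- union(filt_cfg$restrict_to, "ccds")
  }

  ## analysis regions: exome = capture (optionally ∩ CCDS);
  ## panel = panel ∩ capture (optionally ∩ CCDS)
  exome_region <- regions$capture
  panel_region <- region_intersect(panel_rs, regions$capture, name = "panel")
  if (cfg$ccds_restrict) {
    exome_region <- region_intersect(exome_region, regions$ccds,
                                     name = "exome")
    panel_region <- region_intersect(panel_region, regions$ccds,
                                     name = "panel")
  }

  filt <- run_filter_cascade(variants, filt_cfg, regions)
  profiles <- read_coverage_beds(cfg$coverage)
  exposure <- build_exposure_table(
    profiles, list(exome = exome_region, panel = panel_region),
    samples = pops$sample_id)
  pb <- population_burden(filt$events, exposure, pops, panel_region)
  fit <- burden_test(pb, fisher_reference = cfg$fisher_reference,
                     mw_reference = cfg$mw_reference,
                     fisher_mode = cfg$fisher_mode,
                     min_samples = cfg$min_samples)

  tables <- list(
    exome_counts = as_tibble(pb)[, c("population", "sample_id", "M", "L")],
    panel_summary = tidy(fit) |>
      mutate(events_pct = 100 * .data$x_obs /
               max(sum(.data$x_obs), 1)) |>
      select("population", "n", "x_obs", "events_pct", "carriers",
             "carrier_pct"),
    observed_expected = tidy(fit) |>
      mutate(observed_per_individual = .data$x_obs / .data$n,
             expected_per_individual = .data$expected / .data$n) |>
      select("population", "n", "x_obs", "expected", "interval_lo",
             "interval_hi", "observed_per_individual",
             "expected_per_individual", "p_poisson")
  )

  bundle <- structure(list(filter = filt, exposure = exposure, pb = pb,
                           fit = fit, tables = tables,
                           regions = c(regions, list(panel = panel_region,
                                                     exome = exome_region)),
                           config = cfg),
                      class = "burden_run")
  if (!is.null(cfg$out_dir)) write_run_bundle(bundle, cfg$out_dir)
  bundle
}

write_run_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    abort(sprintf("failed writing result bundle (%s); partial outputs removed",
                  conditionMessage(e)))
  }
  tryCatch({
    emit <- function(df, name) {
      p <- file.path(out_dir, name)
      write_tsv(df, p)
      written <<- c(written, p)
    }
    emit(bundle$filter$report, "filter_report.tsv")
    emit(bundle$filter$dispositions, "dispositions.tsv")
    emit(bundle$exposure, "exposure.tsv")
    emit(as_tibble(bundle$pb), "burden_per_sample.tsv")
    emit(bundle$tables$exome_counts, "exome_counts.tsv")
    emit(bundle$tables$panel_summary, "panel_summary.tsv")
    emit(bundle$tables$observed_expected, "observed_expected.tsv")
    p <- file.path(out_dir, "results.tsv")
    write_results(bundle$fit, p)
    written <- c(written, p)
    cfg <- bundle$config
    manifest <- list(cohort = cfg$cohort,
                     thresholds = unclass(cfg$filter),
                     ccds_restrict = cfg$ccds_restrict,
                     fisher_mode = cfg$fisher_mode,
                     n_samples = nrow(as_tibble(bundle$pb)),
                     n_variants_surviving = nrow(bundle$filter$variants),
                     n_events = nrow(bundle$filter$events))
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, error = on_fail)
  invisible(out_dir)
}

#' @export
print.burden_run <- function(x, ...) {
  cat(sprintf("<burden_run> cohort '%s'\n", x$config$cohort))
  print(x$filter$report)
  print(x$fit)
  invisible(x)
}

#' Pooled meta-analysis over several cohort runs
#'
#' Runs (or accepts) per-cohort pipelines and pools their per-sample
#' burden records with [meta_pooled()]: counts and exposures are summed
#' across cohorts per population and the single-cohort tests are applied
#' to the pooled aggregates.
#'
#' @param cfgs List (>= 2) of [run_config()]s or `burden_run` bundles.
#' @param ... Passed to [burden_test()] via [meta_pooled()].
#' @return A `burden_meta` object (see [meta_pooled()]) with the
#'   per-cohort bundles attached as `runs`.
#' @export
run_meta <- function(cfgs, ...) {
  if (!is.list(cfgs) || length(cfgs) < 2) {
    abort("meta-analysis needs >= 2 cohorts; use run_full() for one")
  }
  runs <- lapply(cfgs, function(cfg) {
    if (inherits(cfg, "burden_run")) cfg else run_full(cfg)
  })
  names(runs) <- vapply(runs, function(r) r$config$cohort, character(1))
  pbs <- lapply(runs, function(r) r$pb)
  meta <- meta_pooled(pbs, ...)
  meta$runs <- runs
  meta
}
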
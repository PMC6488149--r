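#' Filter configuration for the truncating-variant cascade
#'
#' Thresholds mirror a stringent germline rare-variant workflow: genotypes
#' below a minimal read depth are treated as missing; sites with too many
#' missing genotypes are dropped; only protein-truncating consequence
#' classes are kept; variants common in any reference population are
#' excluded; long indels, low-depth carrier calls, and variants in
#' repeat/duplication masks or outside the capture territory are removed.
#' Every filter can be neutralized individually (e.g. `maf_max = 1` or
#' `masks = character(0)`).
#'
#' @param genotype_depth_min Genotype calls with depth below this are
#'   missing (default 3).
#' @param site_missing_rate_max Drop a variant when its fraction of missing
#'   genotypes exceeds this (strict `>`, default 0.1).
#' @param maf_max Drop a variant when any configured reference-population
#'   frequency exceeds this (strict `>`, default 0.02). Unknown frequency
#'   never removes.
#' @param indel_length_max Drop indels longer than this many bp (strict
#'   `>`, default 20).
#' @param variant_depth_min A carrier's event is dropped when the carrier's
#'   read depth at the variant is below this (default 15); the variant
#'   itself is dropped only when no carrier attains it.
#' @param truncating_classes Consequence classes retained as
#'   protein-truncating.
#' @param masks Names of region sets whose positions are excluded.
#' @param restrict_to Names of region sets a variant must fall inside
#'   (capture; plus CCDS in harmonized mode).
#' @return A `filter_config` list.
#' @export
filter_config <- function(genotype_depth_min = 3,
                          site_missing_rate_max = 0.1,
                          maf_max = 0.02,
                          indel_length_max = 20,
                          variant_depth_min = 15,
                          truncating_classes = panelburden::truncating_classes(),
                          masks = c("tandem_repeat", "segdup"),
                          restrict_to = "capture") {
  stopifnot(genotype_depth_min >= 0, variant_depth_min >= 0,
            indel_length_max >= 0,
            maf_max > 0, maf_max <= 1,
            site_missing_rate_max >= 0, site_missing_rate_max <= 1)
  structure(list(genotype_depth_min = genotype_depth_min,
                 site_missing_rate_max = site_missing_rate_max,
                 maf_max = maf_max,
                 indel_length_max = indel_length_max,
                 variant_depth_min = variant_depth_min,
                 truncating_classes = truncating_classes,
                 masks = masks,
                 restrict_to = restrict_to),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config>\n")
  cat(sprintf("  genotype depth >= %s, site missing rate <= %s\n",
              x$genotype_depth_min, x$site_missing_rate_max))
  cat(sprintf("  MAF <= %s; indel length <= %s bp; carrier depth >= %s\n",
              x$maf_max, x$indel_length_max, x$variant_depth_min))
  cat(sprintf("  truncating classes: %s\n",
              paste(x$truncating_classes, collapse = ", ")))
  cat(sprintf("  masks: %s; restrict to: %s\n",
              paste(x$masks, collapse = ", "),
              paste(x$restrict_to, collapse = ", ")))
  invisible(x)
}

#' Genotype missingness filter
#'
#' Recodes genotype calls with read depth below `genotype_depth_min` (or
#' unknown depth) as missing, then drops variants whose missing fraction
#' strictly exceeds `site_missing_rate_max`.
#'
#' @param variants Variant tibble from [read_vcf()].
#' @param cfg A [filter_config()].
#' @return The variant tibble with recoded `calls`, rows failing the
#'   missingness threshold removed, and a `missing_rate` column added.
#' @export
apply_genotype_missingness <- function(variants, cfg = filter_config()) {
  if (nrow(variants) > 0 &&
      any(map_int(variants$calls, nrow) == 0)) {
    abort("variant with zero samples")
  }
  variants$calls <- lapply(variants$calls, function(cc) {
    low <- is.na(cc$depth) | cc$depth < cfg$genotype_depth_min
    cc$genotype[low] <- "missing"
    cc
  })
  variants$missing_rate <- map_dbl(variants$calls, function(cc) {
    mean(cc$genotype == "missing")
  })
  variants[variants$missing_rate <= cfg$site_missing_rate_max, , drop = FALSE]
}

#' Protein-truncating classification
#'
#' @param consequence Character vector of consequence classes.
#' @param cfg A [filter_config()].
#' @return Logical: `TRUE` iff the class is in `cfg$truncating_classes`.
#' @export
classify_truncating <- function(consequence, cfg = filter_config()) {
  consequence %in% cfg$truncating_classes
}

#' Minor-allele-frequency filter
#'
#' A variant is removed when any configured reference-population frequency
#' strictly exceeds `maf_max`; sources with no reported frequency never
#' remove (unknown is not evidence of commonness).
#'
#' @param variants Variant tibble.
#' @param cfg A [filter_config()].
#' @return Logical keep-vector (TRUE = retained).
#' @export
apply_maf_filter <- function(variants, cfg = filter_config()) {
  fc <- freq_columns(variants)
  if (length(fc) == 0 || nrow(variants) == 0) {
    return(rep(TRUE, nrow(variants)))
  }
  af <- as.matrix(variants[, fc, drop = FALSE])
  if (any(af < 0 | af > 1, na.rm = TRUE)) {
    abort("allele frequency outside [0, 1]")
  }
  af[is.na(af)] <- -1
  apply(af, 1, max) <= cfg$maf_max
}

#' Structural and region filters
#'
#' Applies, in order: indel-length cutoff, carrier-depth requirement,
#' exclusion masks, and region restriction. The carrier-depth rule is
#' per-event: a carrier whose read depth at the variant is below
#' `variant_depth_min` loses that event; the variant is removed outright
#' only when it has carriers and none attains the depth.
#'
#' @param variants Variant tibble (with `calls`).
#' @param cfg A [filter_config()].
#' @param regions Named list of `region_set`s covering `cfg$masks` and
#'   `cfg$restrict_to`.
#' @return Character vector per variant: `NA` for retained, else the name
#'   of the first removing filter (`"long_indel"`, `"carrier_depth"`,
#'   `"masked_region"`, `"outside_restriction"`).
#' @export
apply_structural_filters <- function(variants, cfg = filter_config(),
                                     regions = list()) {
  n <- nrow(variants)
  removed_by <- rep(NA_character_, n)
  if (n == 0) return(removed_by)

  long_indel <- indel_length(variants$ref, variants$alt) > cfg$indel_length_max

  carrier_fail <- map_lgl(variants$calls, function(cc) {
    carriers <- cc$genotype %in% c("het", "hom_alt")
    any(carriers) &&
      !any(carriers & !is.na(cc$depth) & cc$depth >= cfg$variant_depth_min)
  })

  pos0 <- variants$pos - 1
  masked <- rep(FALSE, n)
  for (m in cfg$masks) {
    rs <- regions[[m]]
    if (is.null(rs)) abort(sprintf("mask region set '%s' not supplied", m))
    masked <- masked | region_member(variants$chrom, pos0, rs,
                                     check_contigs = FALSE)
  }
  outside <- rep(FALSE, n)
  for (r in cfg$restrict_to) {
    rs <- regions[[r]]
    if (is.null(rs)) {
      abort(sprintf("restriction region set '%s' not supplied", r))
    }
    assert_contigs(variants$chrom, rs, what = r)
    outside <- outside | !region_member(variants$chrom, pos0, rs,
                                        check_contigs = FALSE)
  }

  removed_by[outside] <- "outside_restriction"
  removed_by[masked] <- "masked_region"
  removed_by[carrier_fail] <- "carrier_depth"
  removed_by[long_indel] <- "long_indel"
  removed_by
}

cascade_filters <- c("genotype_missingness", "truncating_class",
                     "allele_frequency", "long_indel", "carrier_depth",
                     "masked_region", "outside_restriction")

#' Run the full variant-filter cascade
#'
#' Applies, in fixed order: genotype missingness, truncating
#' classification, reference-population frequency, then the structural and
#' region filters. Produces the surviving variants, the per-(sample,
#' variant) mutation events (carriers with adequate depth), a per-filter
#' accounting report, and a per-variant disposition trace in which each
#' removed variant is charged to exactly one filter.
#'
#' @param variants Variant tibble from [read_vcf()].
#' @param cfg A [filter_config()].
#' @param regions Named list of `region_set`s; must cover `cfg$masks` and
#'   `cfg$restrict_to`.
#' @return A `filter_result` list: `variants` (surviving rows), `events`
#'   (tibble `sample_id`, `variant_id`, `chrom`, `pos`, `depth`), `report`
#'   (tibble `filter`, `n_input`, `n_removed`, `n_surviving`),
#'   `dispositions` (tibble `variant_id`, `removed_by`, `NA` = survived).
#' @export
run_filter_cascade <- function(variants, cfg = filter_config(),
                               regions = list()) {
  for (need in c(cfg$masks, cfg$restrict_to)) {
    if (is.null(regions[[need]])) {
      abort(sprintf("required region set '%s' not supplied", need))
    }
  }
  disposition <- setNames(rep(NA_character_, nrow(variants)),
                          variants$variant_id)
  report <- list()
  tally <- function(stage, n_in, n_out) {
    report[[stage]] <<- tibble(filter = stage, n_input = n_in,
                               n_removed = n_in - n_out, n_surviving = n_out)
  }

  ## 1. genotype missingness
  n_in <- nrow(variants)
  variants <- apply_genotype_missingness(variants, cfg)
  disposition[setdiff(names(disposition[is.na(disposition)]),
                      variants$variant_id)] <- "genotype_missingness"
  tally("genotype_missingness", n_in, nrow(variants))

  ## 2. truncating class
  n_in <- nrow(variants)
  keep <- classify_truncating(variants$consequence, cfg)
  disposition[variants$variant_id[!keep]] <- "truncating_class"
  variants <- variants[keep, , drop = FALSE]
  tally("truncating_class", n_in, nrow(variants))

  ## 3. reference-population frequency
  n_in <- nrow(variants)
  keep <- apply_maf_filter(variants, cfg)
  disposition[variants$variant_id[!keep]] <- "allele_frequency"
  variants <- variants[keep, , drop = FALSE]
  tally("allele_frequency", n_in, nrow(variants))

  ## 4. structural & region filters
  removed_by <- apply_structural_filters(variants, cfg, regions)
  for (stage in c("long_indel", "carrier_depth", "masked_region",
                  "outside_restriction")) {
    n_in <- nrow(variants)
    hit <- !is.na(removed_by) & removed_by == stage
    disposition[variants$variant_id[hit]] <- stage
    variants <- variants[!hit, , drop = FALSE]
    removed_by <- removed_by[!hit]
    tally(stage, n_in, nrow(variants))
  }

  events <- extract_events(variants, cfg)
  structure(list(variants = variants,
                 events = events,
                 report = bind_rows(report)[match(cascade_filters,
                                                  names(report)), ],
                 dispositions = tibble(variant_id = names(disposition),
                                       removed_by = unname(disposition))),
            class = "filter_result")
}

## mutation events: (sample, variant) pairs where the sample carries the
## allele and the carrier's depth meets the variant-depth threshold
extract_events <- function(variants, cfg) {
  if (nrow(variants) == 0) {
    return(tibble(sample_id = character(), variant_id = character(),
                  chrom = character(), pos = numeric(), depth = numeric()))
  }
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    cc <- variants$calls[[i]]
    keep <- cc$genotype %in% c("het", "hom_alt") &
      !is.na(cc$depth) & cc$depth >= cfg$variant_depth_min
    if (!any(keep)) return(NULL)
    tibble(sample_id = cc$sample_id[keep],
           variant_id = variants$variant_id[i],
           chrom = variants$chrom[i],
           pos = variants$pos[i],
           depth = cc$depth[keep])
  })
  bind_rows(rows)
}

#' @export
print.filter_result <- function(x, ...) {
  cat("<filter_result>\n")
  print(x$report)
  cat(sprintf("  %d surviving variants, %d mutation events\n",
              nrow(x$variants), nrow(x$events)))
  invisible(x)
}

#' Write a filter report as TSV
#' @param result A `filter_result` from [run_filter_cascade()].
#' @param path Output path for the per-filter report.
#' @param dispositions_path Optional path for the per-variant trace.
#' @export
write_filter_report <- function(result, path, dispositions_path = NULL) {
  write_tsv(result$report, path)
  if (!is.null(dispositions_path)) {
    write_tsv(result$dispositions, dispositions_path)
  }
  invisible(path)
}
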
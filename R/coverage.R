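#' Per-sample coverage profiles
#'
#' A coverage profile records, for one sample, the genomic intervals whose
#' positions qualify as callable: read depth at or above the calling
#' threshold (15 by convention here) under the upstream quality gates
#' (mapping quality > 20, base quality > 13, anomalous read pairs ignored).
#' Profiles are precomputed inputs — this package never parses alignments;
#' the quality gates are part of the profile-production contract.
#'
#' `read_coverage_beds()` reads one qualifying-interval BED per sample;
#' `depth_to_intervals()` converts a per-base depth table (1-based
#' positions) into qualifying intervals at a stated threshold.
#'
#' @param paths Named character vector of BED paths; names are sample ids
#'   (unnamed paths use the file name stem).
#' @return A `coverage_profiles` tibble with columns `sample_id`, `chrom`,
#'   `start`, `end` (0-based half-open qualifying intervals).
#' @export
read_coverage_beds <- function(paths) {
  ids <- names(paths) %||% rep(NA_character_, length(paths))
  ids[is.na(ids) | !nzchar(ids)] <-
    tools::file_path_sans_ext(basename(paths[is.na(ids) | !nzchar(ids)]))
  out <- purrr::map2(paths, ids, function(p, id) {
    rs <- read_bed(p, name = id)
    mutate(as_tibble(rs), sample_id = id)
  })
  new_coverage(bind_rows(out))
}

new_coverage <- function(df) {
  out <- as_tibble(df[, c("sample_id", "chrom", "start", "end")])
  class(out) <- c("coverage_profiles", class(tibble()))
  out
}

#' @rdname read_coverage_beds
#' @param depth_table Data frame with columns `chrom`, `pos` (1-based),
#'   `depth`, e.g. `samtools depth` output.
#' @param min_depth Depth threshold: positions with `depth >= min_depth`
#'   qualify.
#' @param sample_id Sample the table belongs to.
#' @export
depth_to_intervals <- function(depth_table, min_depth = 15,
                               sample_id = "sample") {
  stopifnot(all(c("chrom", "pos", "depth") %in% names(depth_table)))
  keep <- depth_table[depth_table$depth >= min_depth, , drop = FALSE]
  if (nrow(keep) == 0) {
    return(new_coverage(tibble(sample_id = character(), chrom = character(),
                               start = numeric(), end = numeric())))
  }
  rs <- region_set(tibble(chrom = keep$chrom, start = keep$pos - 1,
                          end = keep$pos), name = sample_id)
  new_coverage(mutate(as_tibble(rs), sample_id = sample_id))
}

#' @rdname read_coverage_beds
#' @param path Path to a 3-column per-base depth TSV
#'   (`chrom`, `pos`, `depth`; 1-based, with or without header).
#' @export
read_depth_table <- function(path, min_depth = 15,
                             sample_id = tools::file_path_sans_ext(basename(path))) {
  first <- readLines(path, n = 1)
  has_header <- str_detect(first, "chrom")
  df <- read_tsv(path, col_names = if (has_header) TRUE else c("chrom", "pos", "depth"),
                 skip = if (has_header) 0 else 0, show_col_types = FALSE)
  if (has_header) names(df)[1:3] <- c("chrom", "pos", "depth")
  depth_to_intervals(df, min_depth = min_depth, sample_id = sample_id)
}

coverage_samples <- function(profiles) unique(profiles$sample_id)

profile_region_set <- function(profiles, sample) {
  rows <- profiles[profiles$sample_id == sample, , drop = FALSE]
  region_set(tibble(chrom = rows$chrom, start = rows$start, end = rows$end),
             name = sample)
}

#' Callable length of a region for one profile
#'
#' The number of positions that both fall in `region` and qualify in the
#' coverage profile — the per-individual exposure denominator of the
#' background mutation rate (exome-wide `L`) and the panel exposure (`l`).
#'
#' @param profile A `region_set` of qualifying intervals, or a
#'   `coverage_profiles` tibble holding exactly one sample.
#' @param region A `region_set` to query.
#' @return Integer number of callable positions.
#' @export
callable_length <- function(profile, region) {
  if (inherits(profile, "coverage_profiles")) {
    ids <- coverage_samples(profile)
    if (length(ids) > 1) abort("profile must hold exactly one sample")
    profile <- if (length(ids) == 0) {
      new_region_set(tibble(chrom = character(), start = numeric(),
                            end = numeric()))
    } else {
      profile_region_set(profile, ids)
    }
  }
  profile <- as_region_set(profile)
  region <- as_region_set(region)
  if (nrow(profile) > 0 && nrow(region) > 0) {
    assert_contigs(profile$chrom, region)
  }
  region_size(region_intersect(profile, region))
}

#' Exposure table: callable length per (sample, region)
#'
#' Computes the complete table of callable lengths for every sample in the
#' coverage profiles crossed with every named region set. By convention the
#' burden analysis queries a region named `"exome"` (the capture territory)
#' and `"panel"` (the gene panel pre-intersected with the capture region,
#' and with CCDS when cross-cohort harmonization is on).
#'
#' @param profiles A `coverage_profiles` tibble (all samples).
#' @param regions Named list of `region_set`s.
#' @param samples Samples that must be present; defaults to those in
#'   `profiles`. A requested sample with no profile is an error.
#' @return Tibble `sample_id`, `region`, `callable_length`.
#' @export
build_exposure_table <- function(profiles, regions,
                                 samples = coverage_samples(profiles)) {
  stopifnot(is.list(regions), !is.null(names(regions)))
  missing_samples <- setdiff(samples, coverage_samples(profiles))
  if (length(missing_samples) > 0) {
    abort(sprintf("no coverage profile for sample(s): %s",
                  paste(missing_samples, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(sample_id = samples, region = names(regions))
  grid$callable_length <- map2_dbl_(grid$sample_id, grid$region,
    function(s, r) callable_length(profile_region_set(profiles, s),
                                   regions[[r]]))
  grid
}

map2_dbl_ <- function(x, y, f) {
  vapply(seq_along(x), function(i) f(x[[i]], y[[i]]), numeric(1))
}

#' Write/read an exposure table as TSV
#' @param exposure Tibble from [build_exposure_table()].
#' @param path Output/input path.
#' @export
write_exposure <- function(exposure, path) {
  write_tsv(exposure, path)
  invisible(path)
}

#' @rdname write_exposure
#' @export
read_exposure <- function(path) {
  read_tsv(path, col_types = cols(sample_id = col_character(),
                                  region = col_character(),
                                  callable_length = col_double()))
}
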
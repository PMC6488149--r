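#' Genomic region sets
#'
#' A `region_set` is a tibble of half-open, 0-based genomic intervals
#' (`chrom`, `start`, `end`) that is kept normalized: sorted, with
#' overlapping or abutting intervals on the same chromosome merged.
#' All capture regions, gene panels, exclusion masks and CCDS regions are
#' represented this way; interval algebra is strand-agnostic.
#'
#' @param chrom Character vector of chromosome names, or a data frame with
#'   columns `chrom`, `start`, `end`.
#' @param start,end Integer-ish vectors; intervals are `[start, end)`,
#'   0-based. Required unless `chrom` is a data frame.
#' @param name Label for the set (e.g. `"capture"`, `"panel"`,
#'   `"tandem_repeat"`).
#' @return A normalized `region_set` tibble.
#' @examples
#' region_set(c("chr1", "chr1"), c(0, 5), c(10, 20))
#' @export
region_set <- function(chrom, start = NULL, end = NULL, name = "regions") {
  if (is.data.frame(chrom)) {
    df <- chrom
    stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  } else {
    df <- tibble(chrom = as.character(chrom),
                 start = as.numeric(start), end = as.numeric(end))
  }
  bad <- which(df$start >= df$end)
  if (length(bad) > 0) {
    abort(sprintf("invalid interval (start >= end) at row %d: %s:%s-%s",
                  bad[1], df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]]))
  }
  if (any(df$start < 0)) abort("negative interval start")
  region_normalize(new_region_set(df, name))
}

new_region_set <- function(df, name = "regions") {
  out <- as_tibble(df[, c("chrom", "start", "end")])
  out$chrom <- as.character(out$chrom)
  out$start <- as.numeric(out$start)
  out$end <- as.numeric(out$end)
  class(out) <- c("region_set", class(tibble()))
  attr(out, "region_name") <- name
  out
}

#' @rdname region_set
#' @param x Object to coerce or test.
#' @export
is_region_set <- function(x) inherits(x, "region_set")

#' @rdname region_set
#' @export
as_region_set <- function(x, name = "regions") {
  if (is_region_set(x)) return(x)
  region_set(x, name = name)
}

#' Name of a region set
#' @param rs A `region_set`.
#' @return The label the set was created with.
#' @export
region_name <- function(rs) attr(rs, "region_name") %||% "regions"

## 0-based half-open tibble <-> 1-based closed GRanges
rs_to_gr <- function(rs) {
  GenomicRanges::GRanges(
    seqnames = rs$chrom,
    ranges = IRanges::IRanges(start = rs$start + 1, end = rs$end)
  )
}

gr_to_rs <- function(gr, name = "regions") {
  df <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1,
               end = GenomicRanges::end(gr))
  ## lexicographic chrom order: independent of seqlevel insertion order
  new_region_set(df[order(df$chrom, df$start), ], name = name)
}

#' Normalize a region set
#'
#' Sorts intervals and merges any that overlap or abut. Idempotent and
#' independent of input order.
#'
#' @param rs A `region_set` (or coercible data frame).
#' @return A normalized `region_set`.
#' @export
region_normalize <- function(rs) {
  name <- region_name(rs)
  if (nrow(rs) == 0) return(new_region_set(rs, name))
  gr_to_rs(GenomicRanges::reduce(rs_to_gr(rs)), name = name)
}

#' Region set algebra
#'
#' `region_intersect()` returns positions present in both sets (used for
#' kit-intersection harmonization and for clipping panels/coverage to the
#' capture territory); `region_subtract()` removes the second set from the
#' first; `region_union()` merges the two.
#'
#' @param a,b `region_set` objects (or coercible data frames).
#' @param name Label for the result; defaults to a derived label.
#' @return A normalized `region_set`.
#' @examples
#' a <- region_set("chr1", 0, 10)
#' b <- region_set("chr1", 5, 20)
#' region_intersect(a, b) # chr1:5-10
#' @export
region_intersect <- function(a, b, name = NULL) {
  a <- as_region_set(a); b <- as_region_set(b)
  name <- name %||% paste0(region_name(a), "&", region_name(b))
  ## disjoint chromosome sets are a valid empty intersection, not an error
  gr <- suppressWarnings(GenomicRanges::intersect(rs_to_gr(a), rs_to_gr(b),
                                                  ignore.strand = TRUE))
  gr_to_rs(gr, name = name)
}

#' @rdname region_intersect
#' @export
region_subtract <- function(a, b, name = NULL) {
  a <- as_region_set(a); b <- as_region_set(b)
  name <- name %||% region_name(a)
  gr <- suppressWarnings(GenomicRanges::setdiff(rs_to_gr(a), rs_to_gr(b),
                                                ignore.strand = TRUE))
  gr_to_rs(gr, name = name)
}

#' @rdname region_intersect
#' @export
region_union <- function(a, b, name = NULL) {
  a <- as_region_set(a); b <- as_region_set(b)
  name <- name %||% paste0(region_name(a), "|", region_name(b))
  gr <- suppressWarnings(c(rs_to_gr(a), rs_to_gr(b)))
  gr_to_rs(GenomicRanges::reduce(gr), name = name)
}

#' Total length of a region set
#'
#' @param rs A `region_set`.
#' @return Total number of positions covered, `sum(end - start)`.
#' @export
region_size <- function(rs) {
  rs <- as_region_set(rs)
  sum(rs$end - rs$start)
}

#' Test positions for membership in a region set
#'
#' @param chrom Chromosome names of the query positions.
#' @param pos0 0-based positions (for a VCF record at 1-based position
#'   `pos`, pass `pos - 1`; for indels this is the anchor base).
#' @param rs A `region_set`.
#' @param check_contigs If `TRUE` (default), error when the query and the
#'   region set share no chromosome names (e.g. `chr1` vs `1`); silent
#'   renaming is never attempted.
#' @return Logical vector, `TRUE` where the position falls in the set.
#' @export
region_member <- function(chrom, pos0, rs, check_contigs = TRUE) {
  rs <- as_region_set(rs)
  if (length(chrom) == 0) return(logical(0))
  if (check_contigs) assert_contigs(chrom, rs)
  if (nrow(rs) == 0) return(rep(FALSE, length(chrom)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos0 + 1, pos0 + 1))
  GenomicRanges::countOverlaps(q, rs_to_gr(rs)) > 0
}

assert_contigs <- function(chrom, rs, what = region_name(rs)) {
  qc <- unique(as.character(chrom))
  rc <- unique(rs$chrom)
  if (length(qc) > 0 && length(rc) > 0 && length(intersect(qc, rc)) == 0) {
    abort(sprintf(
      "contig naming mismatch: query contigs (%s) share no name with region set '%s' (%s); harmonize contig names explicitly",
      paste(head(qc, 3), collapse = ","), what, paste(head(rc, 3), collapse = ",")))
  }
  invisible(TRUE)
}

#' Read a BED file into a region set
#'
#' Accepts 3+ column BED (0-based half-open); extra columns are ignored.
#'
#' @param path Path to a BED file.
#' @param name Label for the resulting set.
#' @return A normalized `region_set`.
#' @export
read_bed <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  raw <- readLines(path)
  raw <- raw[nzchar(raw) & !str_starts(raw, "#") & !str_starts(raw, "track")]
  if (length(raw) == 0) {
    return(new_region_set(tibble(chrom = character(), start = numeric(),
                                 end = numeric()), name))
  }
  fields <- str_split(raw, "\t")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("BED line %d has fewer than 3 columns in %s",
                  which(nf < 3)[1], path))
  }
  df <- tibble(
    chrom = map_chr(fields, 1),
    start = suppressWarnings(as.numeric(map_chr(fields, 2))),
    end = suppressWarnings(as.numeric(map_chr(fields, 3)))
  )
  bad <- which(is.na(df$start) | is.na(df$end) | df$start >= df$end)
  if (length(bad) > 0) {
    abort(sprintf("invalid BED interval at line %d of %s: '%s'",
                  bad[1], path, raw[bad[1]]))
  }
  region_set(df, name = name)
}

#' Write a region set as BED
#'
#' @param rs A `region_set`.
#' @param path Output path.
#' @param names Optional per-interval names (4th BED column).
#' @return `path`, invisibly.
#' @export
write_bed <- function(rs, path, names = NULL) {
  rs <- as_region_set(rs)
  lines <- if (is.null(names)) {
    sprintf("%s\t%d\t%d", rs$chrom, as.integer(rs$start), as.integer(rs$end))
  } else {
    sprintf("%s\t%d\t%d\t%s", rs$chrom, as.integer(rs$start),
            as.integer(rs$end), names)
  }
  writeLines(lines, path)
  invisible(path)
}
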
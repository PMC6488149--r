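#' Annotation key map for annotated VCFs
#'
#' The pipeline consumes functional consequences and reference-population
#' allele frequencies from INFO keys written by an annotation tool; it never
#' recomputes them. The default dialect is ANNOVAR's refGene/popfreq keys:
#' `Func.refGene` (splicing detection), `ExonicFunc.refGene` (exonic class),
#' and one key per frequency source. Frequency keys are named here by the
#' column they populate (`af_1000g`, `af_esp`, `af_exac`); any number of
#' sources may be configured.
#'
#' @param func_key INFO key holding the genomic-context class (value
#'   `splicing` maps to the `splice_site` consequence).
#' @param exonic_key INFO key holding the exonic functional class
#'   (`stopgain`, `stoploss`, `frameshift_insertion`, ...).
#' @param freq_keys Named character vector: output column name -> INFO key.
#' @return A `vcf_key_map` list.
#' @export
vcf_key_map <- function(func_key = "Func.refGene",
                        exonic_key = "ExonicFunc.refGene",
                        freq_keys = c(af_1000g = "1000g2015aug_all",
                                      af_esp = "esp6500siv2_all",
                                      af_exac = "ExAC_nontcga_ALL")) {
  stopifnot(is.character(freq_keys), !is.null(names(freq_keys)))
  structure(list(func_key = func_key, exonic_key = exonic_key,
                 freq_keys = freq_keys),
            class = "vcf_key_map")
}

#' Consequence classes treated as protein-truncating
#' @return Character vector of the four truncating classes.
#' @export
truncating_classes <- function() {
  c("splice_site", "frameshift_indel", "stopgain", "stoploss")
}

map_consequence <- function(func_val, exonic_val) {
  cons <- rep("other", length(exonic_val))
  ex <- tolower(ifelse(is.na(exonic_val), "", exonic_val))
  cons[str_detect(ex, "stopgain")] <- "stopgain"
  cons[str_detect(ex, "stoploss")] <- "stoploss"
  cons[str_detect(ex, "frameshift")] <- "frameshift_indel"
  fn <- tolower(ifelse(is.na(func_val), "", func_val))
  cons[str_detect(fn, "splicing")] <- "splice_site"
  cons
}

## pick the k-th comma-separated element (per-allele INFO values), else the
## whole value when the field is not per-allele
nth_or_all <- function(x, k) {
  ifelse(is.na(x), NA_character_,
         vapply(seq_along(x), function(i) {
           parts <- strsplit(x[i], ",", fixed = TRUE)[[1]]
           if (length(parts) >= k[i]) parts[k[i]] else parts[1]
         }, character(1)))
}

classify_genotype <- function(gt, allele_index) {
  ## gt like "0/1", "1|1", "./."; allele_index is the decomposed ALT's
  ## original index (1-based within the record's ALT list)
  out <- character(length(gt))
  for (i in seq_along(gt)) {
    g <- gt[i]
    if (is.na(g) || str_detect(g, stringr::fixed("."))) {
      out[i] <- "missing"
      next
    }
    alleles <- strsplit(g, "[/|]")[[1]]
    k <- sum(alleles == as.character(allele_index[i]))
    out[i] <- c("hom_ref", "het", "hom_alt")[k + 1]
  }
  out
}

#' Read an annotated VCF into a variant tibble
#'
#' Returns one row per alternate allele (multi-allelic records are
#' decomposed when `decompose = TRUE`), with the consequence class and
#' allele frequencies mapped from INFO keys and per-sample genotype calls
#' nested in a `calls` list-column. Records lacking a recognized
#' consequence key get `consequence = "other"`; frequency keys absent from
#' a record yield `NA` (unknown, *not* zero — an unknown frequency later
#' passes the rarity filter).
#'
#' @param path Path to a VCF 4.x file (plain or bgzipped).
#' @param key_map A [vcf_key_map()].
#' @param decompose Emit one row per ALT allele (default `TRUE`).
#' @return A tibble with columns `variant_id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `consequence`, one `af_*` column per configured
#'   frequency source, and `calls` (tibble of `sample_id`, `genotype`,
#'   `depth` per variant).
#' @export
read_vcf <- function(path, key_map = vcf_key_map(), decompose = TRUE) {
  if (!file.exists(path)) abort(sprintf("VCF not found: %s", path))
  first <- readLines(path, n = 1)
  if (!str_starts(first, "##fileformat=VCF")) {
    abort(sprintf("malformed VCF (line 1 is not a ##fileformat header): %s",
                  path))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(empty_variant_tbl(key_map))
  }
  func_val <- vcfR::extract.info(v, element = key_map$func_key)
  exonic_val <- vcfR::extract.info(v, element = key_map$exonic_key)
  freq_raw <- lapply(key_map$freq_keys, function(k) {
    vcfR::extract.info(v, element = k)
  })
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  samples <- colnames(gt)

  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  if (!decompose && any(n_alt > 1)) {
    abort("multi-allelic record found with decompose = FALSE")
  }
  rec <- rep(seq_len(nrow(fix)), n_alt)
  aidx <- unlist(lapply(n_alt, seq_len))
  alt <- unlist(alt_list)

  out <- tibble(
    chrom = fix$CHROM[rec],
    pos = as.numeric(fix$POS[rec]),
    ref = fix$REF[rec],
    alt = alt,
    consequence = map_consequence(func_val[rec], exonic_val[rec])
  )
  for (nm in names(key_map$freq_keys)) {
    vals <- nth_or_all(freq_raw[[nm]][rec], aidx)
    out[[nm]] <- suppressWarnings(as.numeric(vals))
  }
  if (any(out$pos < 1)) abort("VCF position < 1")
  if (any(out$alt == out$ref)) abort("ALT allele identical to REF")

  out$variant_id <- sprintf("%s:%d:%s:%s", out$chrom, as.integer(out$pos),
                            out$ref, out$alt)
  out$calls <- lapply(seq_len(nrow(out)), function(i) {
    tibble(sample_id = samples,
           genotype = classify_genotype(gt[rec[i], ], rep(aidx[i],
                                                          length(samples))),
           depth = as.numeric(dp[rec[i], ]))
  })
  attr(out, "freq_cols") <- names(key_map$freq_keys)
  attr(out, "samples") <- samples
  select(out, "variant_id", everything())
}

empty_variant_tbl <- function(key_map = vcf_key_map()) {
  out <- tibble(variant_id = character(), chrom = character(),
                pos = numeric(), ref = character(), alt = character(),
                consequence = character())
  for (nm in names(key_map$freq_keys)) out[[nm]] <- numeric()
  out$calls <- list()
  attr(out, "freq_cols") <- names(key_map$freq_keys)
  out
}

#' Length difference of an indel
#'
#' @param ref,alt Allele strings.
#' @return `abs(nchar(ref) - nchar(alt))`; 0 for substitutions.
#' @export
indel_length <- function(ref, alt) abs(nchar(ref) - nchar(alt))

freq_columns <- function(variants) {
  fc <- attr(variants, "freq_cols")
  if (!is.null(fc)) return(intersect(fc, names(variants)))
  grep("^af_", names(variants), value = TRUE)
}
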
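#' Scenario configuration for synthetic cohorts
#'
#' Defines a multi-population cohort with population-specific exome-wide
#' truncating-mutation rates and a configurable panel enrichment factor,
#' per-sample coverage dropout, contaminating common variants, and decoy
#' variants engineered to fail exactly one filter each — everything needed
#' to exercise every stage of the pipeline with no external data.
#'
#' @param populations Tibble with columns `label`, `n_samples`,
#'   `exome_rate` (truncating events per callable position) and
#'   `panel_enrichment` (multiplicative factor, 1 = no enrichment).
#' @param exome_size Total capture territory in bp.
#' @param panel_size Total panel territory in bp (must fit in the capture).
#' @param n_blocks Number of capture blocks the territory is split into.
#' @param block_gap Uncaptured gap between blocks (bp).
#' @param coverage_dropout Range `c(lo, hi)`: each sample loses a
#'   `runif(lo, hi)` fraction of every capture block.
#' @param common_variant_count Number of contaminating common truncating
#'   variants (exercise the frequency filter).
#' @param common_maf_range Reference-population frequency range for the
#'   common contaminants (must exceed the 2% cutoff to be removed).
#' @param decoys_per_filter Decoy variants per non-frequency filter.
#' @param seed Integer seed; every stochastic step derives from it.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(populations = default_populations(),
                            exome_size = 30e6,
                            panel_size = 1e5,
                            n_blocks = 200,
                            block_gap = 1e4,
                            coverage_dropout = c(0.1, 0.3),
                            common_variant_count = 25,
                            common_maf_range = c(0.05, 0.5),
                            decoys_per_filter = 1,
                            seed = 1) {
  stopifnot(is.data.frame(populations),
            all(c("label", "n_samples", "exome_rate",
                  "panel_enrichment") %in% names(populations)))
  if (panel_size > exome_size) abort("panel_size exceeds exome_size")
  stopifnot(all(populations$exome_rate >= 0),
            all(populations$panel_enrichment >= 0),
            all(populations$n_samples >= 1),
            coverage_dropout[1] >= 0, coverage_dropout[2] < 1,
            coverage_dropout[1] <= coverage_dropout[2],
            n_blocks >= 40)
  block_size <- floor(exome_size / n_blocks)
  gene_len <- floor(panel_size / 19)
  if (gene_len + 2 > floor(0.8 * block_size)) {
    abort("panel genes do not fit inside capture blocks; increase exome_size or n_blocks")
  }
  structure(list(populations = as_tibble(populations),
                 exome_size = exome_size, panel_size = panel_size,
                 n_blocks = n_blocks, block_gap = block_gap,
                 block_size = block_size,
                 coverage_dropout = coverage_dropout,
                 common_variant_count = common_variant_count,
                 common_maf_range = common_maf_range,
                 decoys_per_filter = decoys_per_filter,
                 seed = seed),
            class = "scenario_config")
}

#' @rdname scenario_config
#' @details `default_populations()` emulates a four-population early-onset
#'   TNBC discovery cohort: Blacks carry the highest exome-wide truncating
#'   rate (low single-digit events per exome) while Whites and Hispanics,
#'   not Blacks, are enriched in the breast-cancer panel — the reversal
#'   pattern the burden analysis is designed to detect.
#' @export
default_populations <- function() {
  tibble(label = c("White", "Black", "Hispanic", "Asian"),
         n_samples = c(48, 40, 25, 13),
         exome_rate = c(1.15e-7, 1.6e-7, 1.25e-7, 1.2e-7),
         panel_enrichment = c(5, 1, 3, 1))
}

## deterministic genome geometry shared by all samples of a scenario
scenario_geometry <- function(cfg) {
  bs <- cfg$block_size
  gap <- cfg$block_gap
  starts <- (seq_len(cfg$n_blocks) - 1) * (bs + gap)
  capture <- region_set(tibble(chrom = "chr1", start = starts,
                               end = starts + bs), name = "capture")
  gene_len <- floor(cfg$panel_size / 19)
  extra <- cfg$panel_size - 19 * gene_len
  lens <- rep(gene_len, 19)
  lens[19] <- lens[19] + extra
  gstart <- starts[1:19] + floor(bs / 2) - floor(lens / 2)
  panel <- new_region_set(tibble(chrom = "chr1", start = gstart,
                                 end = gstart + lens), name = "panel")
  mask_center <- function(idx) {
    region_set(tibble(chrom = "chr1",
                      start = starts[idx] + floor(bs / 2) - 1000,
                      end = starts[idx] + floor(bs / 2) + 1000),
               name = "mask")
  }
  tandem <- mask_center(21:25)
  attr(tandem, "region_name") <- "tandem_repeat"
  segdup <- mask_center(26:30)
  attr(segdup, "region_name") <- "segdup"
  ccds <- region_set(tibble(chrom = "chr1",
                            start = starts + floor(0.1 * bs),
                            end = starts + floor(0.9 * bs)), name = "ccds")
  list(capture = capture, panel = panel, panel_genes = breast_panel_genes(),
       tandem_repeat = tandem, segdup = segdup, ccds = ccds,
       block_starts = starts, block_size = bs)
}

## k distinct positions (0-based) drawn uniformly from a region set
sample_positions <- function(rs, k) {
  if (k == 0) return(numeric(0))
  w <- rs$end - rs$start
  total <- sum(w)
  if (total < k) abort("region too small to place requested positions")
  offs <- sort(sample.int(total, k))
  cum <- cumsum(w)
  iv <- findInterval(offs - 1, cum) + 1
  rs$start[iv] + (offs - c(0, cum)[iv] - 1)
}

random_base <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

alt_base <- function(ref) {
  vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
         character(1), USE.NAMES = FALSE)
}

#' Simulate a complete synthetic cohort on disk
#'
#' Writes an annotated VCF, per-sample coverage-profile BEDs, region BEDs
#' (capture, 19-gene panel, tandem-repeat and segmental-duplication masks,
#' CCDS), a population table, and a ground-truth manifest JSON. True
#' truncating events are drawn per sample as Poisson counts with mean
#' `enrichment * exome_rate * l` inside the panel and
#' `exome_rate * (L - l)` outside it (`L`, `l` = the sample's callable
#' positions exome-wide and in the panel), placed uniformly within the
#' sample's callable intervals, annotated to pass every filter. Decoy
#' variants are engineered to fail exactly one named filter each.
#'
#' @param cfg A [scenario_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths) and
#'   `manifest` (the ground truth: `per_sample` counts/exposures,
#'   per-variant `variants` dispositions, parameters).
#' @export
simulate_cohort <- function(cfg = scenario_config(), dir = tempfile("cohort")) {
  stopifnot(inherits(cfg, "scenario_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "coverage"), showWarnings = FALSE)
  set.seed(cfg$seed)
  geo <- scenario_geometry(cfg)

  pops <- cfg$populations
  samples <- tibble(
    sample_id = sprintf("S%03d", seq_len(sum(pops$n_samples))),
    population = rep(pops$label, pops$n_samples),
    exome_rate = rep(pops$exome_rate, pops$n_samples),
    panel_enrichment = rep(pops$panel_enrichment, pops$n_samples)
  )
  n <- nrow(samples)

  ## per-sample coverage: drop a runif fraction of every block
  drop_frac <- runif(n, cfg$coverage_dropout[1], cfg$coverage_dropout[2])
  bs <- geo$block_size
  cov_list <- vector("list", n)
  for (j in seq_len(n)) {
    dlen <- round(drop_frac[j] * bs)
    off <- floor(runif(cfg$n_blocks, 0, bs - dlen + 1))
    s1 <- geo$block_starts
    piece1 <- tibble(chrom = "chr1", start = s1, end = s1 + off)
    piece2 <- tibble(chrom = "chr1", start = s1 + off + dlen, end = s1 + bs)
    cov <- bind_rows(piece1, piece2)
    cov <- cov[cov$start < cov$end, , drop = FALSE]
    cov_list[[j]] <- region_set(cov, name = samples$sample_id[j])
  }

  ## exact per-sample exposures from the generated coverage
  samples$L <- map_dbl(cov_list, function(rs) {
    region_size(region_intersect(rs, geo$capture))
  })
  samples$l <- map_dbl(cov_list, function(rs) {
    region_size(region_intersect(rs, geo$panel))
  })

  ## true events
  masks <- region_union(geo$tandem_repeat, geo$segdup)
  event_rows <- vector("list", n)
  for (j in seq_len(n)) {
    m_j <- rpois(1, samples$panel_enrichment[j] * samples$exome_rate[j] *
                   samples$l[j])
    off_j <- rpois(1, samples$exome_rate[j] * (samples$L[j] - samples$l[j]))
    panel_cov <- region_intersect(cov_list[[j]], geo$panel)
    off_cov <- region_subtract(region_subtract(cov_list[[j]], geo$panel),
                               masks)
    pos0 <- c(if (m_j > 0) sample_positions(panel_cov, m_j),
              if (off_j > 0) sample_positions(off_cov, off_j))
    if (length(pos0) == 0) next
    event_rows[[j]] <- tibble(sample_id = samples$sample_id[j],
                              pos0 = pos0,
                              in_panel = c(rep(TRUE, m_j), rep(FALSE, off_j)))
  }
  events <- bind_rows(event_rows)
  ## enforce unique positions cohort-wide (collisions are vanishingly rare)
  while (any(duplicated(events$pos0))) {
    dup <- which(duplicated(events$pos0))
    events$pos0[dup] <- events$pos0[dup] + 2L
  }

  truncating_mix <- function(k) {
    sample(c("splice_site", "frameshift_indel", "stopgain", "stoploss"),
           k, replace = TRUE, prob = c(0.2, 0.4, 0.35, 0.05))
  }

  if (nrow(events) > 0) {
    events$consequence <- truncating_mix(nrow(events))
    events$af <- ifelse(runif(nrow(events)) < 0.5, NA,
                        round(runif(nrow(events), 0, 0.019), 6))
    events$depth <- sample(20:80, nrow(events), replace = TRUE)
  }

  ## decoys and contaminants, placed off-panel (true counts untouched)
  clean <- region_subtract(region_subtract(geo$capture, geo$panel), masks)
  dk <- cfg$decoys_per_filter
  n_decoy <- 4 * dk + cfg$common_variant_count
  decoy_pos <- sample_positions(clean, n_decoy + 50)
  decoy_pos <- setdiff(decoy_pos, events$pos0)[seq_len(n_decoy)]
  gap_pos <- geo$block_starts[31:(30 + dk)] + bs + floor(cfg$block_gap / 2)
  mask_pos <- sample_positions(geo$tandem_repeat, dk)

  decoys <- bind_rows(
    tibble(pos0 = decoy_pos[seq_len(dk)],
           kind = "high_missingness", disposition = "genotype_missingness"),
    tibble(pos0 = decoy_pos[dk + seq_len(dk)],
           kind = "missense", disposition = "truncating_class"),
    tibble(pos0 = decoy_pos[2 * dk + seq_len(dk)],
           kind = "long_indel", disposition = "long_indel"),
    tibble(pos0 = decoy_pos[3 * dk + seq_len(dk)],
           kind = "low_depth", disposition = "carrier_depth"),
    tibble(pos0 = mask_pos, kind = "masked", disposition = "masked_region"),
    tibble(pos0 = gap_pos, kind = "outside_capture",
           disposition = "outside_restriction"),
    tibble(pos0 = decoy_pos[4 * dk + seq_len(cfg$common_variant_count)],
           kind = "common", disposition = "allele_frequency")
  )

  records <- build_vcf_records(events, decoys, samples, cfg)
  paths <- list(
    vcf = file.path(dir, "cohort.vcf"),
    capture = file.path(dir, "capture.bed"),
    panel = file.path(dir, "panel.bed"),
    tandem_repeat = file.path(dir, "tandem_repeat.bed"),
    segdup = file.path(dir, "segdup.bed"),
    ccds = file.path(dir, "ccds.bed"),
    populations = file.path(dir, "populations.tsv"),
    manifest = file.path(dir, "manifest.json"),
    coverage = setNames(file.path(dir, "coverage",
                                  paste0(samples$sample_id, ".bed")),
                        samples$sample_id)
  )
  write_vcf_records(records, samples$sample_id, paths$vcf, cfg)
  write_bed(geo$capture, paths$capture)
  write_bed(geo$panel, paths$panel, names = geo$panel_genes)
  write_bed(geo$tandem_repeat, paths$tandem_repeat)
  write_bed(geo$segdup, paths$segdup)
  write_bed(geo$ccds, paths$ccds)
  write_tsv(samples[, c("sample_id", "population")], paths$populations)
  for (j in seq_len(n)) write_bed(cov_list[[j]], paths$coverage[[j]])

  counts <- if (nrow(events) > 0) {
    events |>
      group_by(.data$sample_id) |>
      summarise(M_true = dplyr::n(), m_true = sum(.data$in_panel),
                .groups = "drop")
  } else {
    tibble(sample_id = character(), M_true = integer(), m_true = integer())
  }
  per_sample <- counts |>
    right_join(samples[, c("sample_id", "population", "L", "l")],
               by = "sample_id") |>
    mutate(M_true = ifelse(is.na(.data$M_true), 0L, .data$M_true),
           m_true = ifelse(is.na(.data$m_true), 0L, .data$m_true)) |>
    select("sample_id", "population", "L", "l", "M_true", "m_true") |>
    arrange(.data$sample_id)

  manifest <- list(
    params = list(populations = pops, exome_size = cfg$exome_size,
                  panel_size = cfg$panel_size, n_blocks = cfg$n_blocks,
                  coverage_dropout = cfg$coverage_dropout,
                  seed = cfg$seed),
    per_sample = per_sample,
    variants = records$manifest,
    region_sizes = list(capture = region_size(geo$capture),
                        panel = region_size(geo$panel))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(paths = paths, manifest = manifest))
}

## assemble one VCF row per event/decoy with annotation + genotype fields
build_vcf_records <- function(events, decoys, samples, cfg) {
  n <- nrow(samples)
  rows <- list()
  if (nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      e <- events[i, ]
      rows[[length(rows) + 1]] <- list(
        pos0 = e$pos0, class = e$consequence, carrier = e$sample_id,
        carrier_depth = e$depth, af = e$af, kind = "true_event",
        disposition = "pass")
    }
  }
  if (nrow(decoys) > 0) {
    for (i in seq_len(nrow(decoys))) {
      d <- decoys[i, ]
      carrier <- samples$sample_id[1 + (i - 1) %% n]
      rows[[length(rows) + 1]] <- list(
        pos0 = d$pos0,
        class = switch(d$kind, missense = "other",
                       long_indel = "frameshift_indel", "stopgain"),
        carrier = carrier,
        carrier_depth = if (d$kind == "low_depth") 14 else 35,
        af = if (d$kind == "common") {
          round(runif(1, cfg$common_maf_range[1], cfg$common_maf_range[2]), 4)
        } else NA,
        kind = d$kind, disposition = d$disposition)
    }
  }
  ord <- order(vapply(rows, function(r) r$pos0, numeric(1)))
  rows <- rows[ord]

  manifest <- bind_rows(lapply(rows, function(r) {
    tibble(pos = r$pos0 + 1, kind = r$kind, class = r$class,
           carrier = r$carrier, disposition = r$disposition)
  }))
  list(rows = rows, manifest = manifest)
}

write_vcf_records <- function(records, sample_ids, path, cfg) {
  n <- length(sample_ids)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=chr1,length=%d>",
            as.integer(cfg$n_blocks * (cfg$block_size + cfg$block_gap) + 1e6)),
    "##INFO=<ID=Func.refGene,Number=1,Type=String,Description=\"Genomic context\">",
    "##INFO=<ID=ExonicFunc.refGene,Number=1,Type=String,Description=\"Exonic functional class\">",
    "##INFO=<ID=1000g2015aug_all,Number=1,Type=Float,Description=\"1000 Genomes ALL frequency\">",
    "##INFO=<ID=esp6500siv2_all,Number=1,Type=Float,Description=\"ESP6500 frequency\">",
    "##INFO=<ID=ExAC_nontcga_ALL,Number=1,Type=Float,Description=\"ExAC non-TCGA frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  lines <- vapply(records$rows, function(r) {
    ref <- random_base(1)
    alt <- alt_base(ref)
    if (r$class == "frameshift_indel") {
      ins_len <- if (r$kind == "long_indel") 25 else sample(1:10, 1)
      alt <- paste0(ref, paste(random_base(ins_len), collapse = ""))
    }
    info <- if (r$class == "splice_site") {
      "Func.refGene=splicing"
    } else if (r$class == "other") {
      "Func.refGene=exonic;ExonicFunc.refGene=nonsynonymous_SNV"
    } else {
      cls <- switch(r$class, frameshift_indel = "frameshift_insertion",
                    r$class)
      sprintf("Func.refGene=exonic;ExonicFunc.refGene=%s", cls)
    }
    if (!is.na(r$af)) {
      info <- paste0(info, sprintf(";1000g2015aug_all=%s", r$af))
    }
    base_dp <- sample(18:60, n, replace = TRUE)
    gt <- sprintf("0/0:%d", base_dp)
    ci <- match(r$carrier, sample_ids)
    if (r$kind == "high_missingness") {
      ## strictly more than 10% of genotypes at depth < 3, carrier excluded
      k <- ceiling(0.12 * n)
      idx <- setdiff(seq_len(n), ci)[seq_len(k)]
      gt[idx] <- "./.:2"
    }
    gt[ci] <- sprintf("0/1:%d", as.integer(r$carrier_depth))
    paste(c("chr1", as.integer(r$pos0 + 1), ".", ref, alt, ".", "PASS",
            info, "GT:DP", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Count-level simulation of one cohort's burden statistics
#'
#' The generative model of [simulate_cohort()] reduced to its sufficient
#' statistics: per-sample callable lengths under coverage dropout, and
#' Poisson event counts inside and outside the panel. Used by the
#' calibration and power harnesses, where only counts and exposures enter
#' the tests.
#'
#' @param n Samples in the population.
#' @param exome_rate Truncating events per callable position.
#' @param enrichment Panel enrichment factor (1 = null).
#' @param exome_size,panel_size Capture and panel sizes (bp).
#' @param dropout Coverage-dropout range, as in [scenario_config()].
#' @return Tibble `M`, `L`, `m`, `l` with one row per sample.
#' @export
simulate_burden_counts <- function(n = 40, exome_rate = 1.5e-6,
                                   enrichment = 1,
                                   exome_size = 30e6, panel_size = 1e5,
                                   dropout = c(0.1, 0.3)) {
  d <- runif(n, dropout[1], dropout[2])
  L <- round((1 - d) * exome_size)
  l <- round((1 - d) * panel_size)
  m <- rpois(n, enrichment * exome_rate * l)
  M_off <- rpois(n, exome_rate * (L - l))
  tibble(M = m + M_off, L = L, m = m, l = l)
}

#' Calibration/power grid for the Poisson enrichment test
#'
#' Simulates `replicates` independent single-population cohorts from the
#' count-level generative model and applies the full estimation + test
#' path to each: `lambda` estimated exome-wide from that replicate's own
#' events, then the exact two-sided Poisson test of the observed panel
#' count against `lambda * T`. With `enrichment = 1` this is the null
#' calibration harness; with `enrichment > 1` it measures power and rate
#' recovery.
#'
#' @param replicates Number of replicate cohorts (>= 1).
#' @param seed Integer seed.
#' @inheritParams simulate_burden_counts
#' @return Tibble with one row per replicate: `x_obs`, `T`, `lambda_hat`,
#'   `mu` (= `lambda_hat * T`), `p_value`, `enriched` (observed above
#'   expectation).
#' @export
simulate_null_grid <- function(replicates, n = 40, exome_rate = 1.5e-6,
                               enrichment = 1, exome_size = 30e6,
                               panel_size = 1e5, dropout = c(0.1, 0.3),
                               seed = 1) {
  stopifnot(replicates >= 1)
  set.seed(seed)
  ## vectorized across replicates: matrices replicate x sample
  d <- matrix(runif(replicates * n, dropout[1], dropout[2]), replicates, n)
  L <- round((1 - d) * exome_size)
  l <- round((1 - d) * panel_size)
  m <- matrix(rpois(replicates * n, enrichment * exome_rate * l),
              replicates, n)
  M_off <- matrix(rpois(replicates * n, exome_rate * (L - l)),
                  replicates, n)
  x <- rowSums(m)
  T_panel <- rowSums(l)
  lambda_hat <- rowSums(m + M_off) / rowSums(L)
  mu <- lambda_hat * T_panel
  p <- vapply(seq_len(replicates), function(i) {
    poisson_two_sided(x[i], T_panel[i], lambda_hat[i])
  }, numeric(1))
  tibble(replicate = seq_len(replicates), x_obs = x, T = T_panel,
         lambda_hat = lambda_hat, mu = mu, p_value = p,
         enriched = x > mu)
}

#' Two-population reversal-pattern grid
#'
#' Simulates replicate two-population cohorts in which population A has
#' the higher exome-wide rate but no panel enrichment, while population B
#' has a lower exome-wide rate but a panel enrichment factor. For each
#' replicate it records whether the Mann-Whitney exome-wide contrast finds
#' A's burden higher, and whether the Poisson panel test is significant
#' (and in the enrichment direction) in each population — the reversal
#' pattern: exome-wide burden highest in A, panel enrichment only in B.
#'
#' @param replicates Number of replicate cohorts.
#' @param n_a,n_b Samples per population.
#' @param rate_a,rate_b Exome-wide truncating rates (A > B for the
#'   reversal scenario).
#' @param enrichment_a,enrichment_b Panel enrichment factors.
#' @param exome_size,panel_size,dropout As in [simulate_burden_counts()].
#' @param alpha Two-sided significance level (default 0.05).
#' @param seed Integer seed.
#' @return Tibble with per-replicate p-values and a `reversal` flag.
#' @export
simulate_reversal_grid <- function(replicates, n_a = 40, n_b = 40,
                                   rate_a = 1.5e-6, rate_b = 1.0e-6,
                                   enrichment_a = 1, enrichment_b = 5,
                                   exome_size = 30e6, panel_size = 1e5,
                                   dropout = c(0.1, 0.3), alpha = 0.05,
                                   seed = 1) {
  set.seed(seed)
  one <- function() {
    a <- simulate_burden_counts(n_a, rate_a, enrichment_a, exome_size,
                                panel_size, dropout)
    b <- simulate_burden_counts(n_b, rate_b, enrichment_b, exome_size,
                                panel_size, dropout)
    lam_a <- estimate_lambda(a); lam_b <- estimate_lambda(b)
    mu_a <- lam_a * sum(a$l); mu_b <- lam_b * sum(b$l)
    p_a <- poisson_two_sided(sum(a$m), sum(a$l), lam_a)
    p_b <- poisson_two_sided(sum(b$m), sum(b$l), lam_b)
    p_mw <- mannwhitney_burden(a$M, b$M)
    tibble(p_mw = p_mw, a_higher_exome = mean(a$M) > mean(b$M),
           p_pois_a = p_a, a_enriched = sum(a$m) > mu_a,
           p_pois_b = p_b, b_enriched = sum(b$m) > mu_b)
  }
  out <- bind_rows(lapply(seq_len(replicates), function(i) one()))
  out$replicate <- seq_len(replicates)
  out$reversal <- out$a_higher_exome & out$p_mw < alpha &
    out$p_pois_b < alpha & out$b_enriched &
    !(out$p_pois_a < alpha & out$a_enriched)
  out
}
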
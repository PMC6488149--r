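# Fixtures are built in code: small variant tables, inline VCF text, and a
# tiny two-population scenario for the file-level generator.

FREQ_COLS <- c("af_1000g", "af_esp", "af_exac")

# one variant row; carriers described by genotype/depth vectors, padded with
# hom_ref samples so every variant shares the sample set S01..Snn
make_variant <- function(pos, consequence = "stopgain", ref = "A", alt = "T",
                         af_1000g = NA_real_, af_esp = NA_real_,
                         af_exac = NA_real_,
                         genotypes = "het", depths = 30,
                         n_samples = 10, ref_depth = 30, chrom = "chr1") {
  gt <- c(genotypes, rep("hom_ref", n_samples - length(genotypes)))
  dp <- c(depths, rep(ref_depth, n_samples - length(depths)))
  tibble::tibble(
    variant_id = sprintf("%s:%d:%s:%s", chrom, pos, ref, alt),
    chrom = chrom, pos = as.numeric(pos), ref = ref, alt = alt,
    consequence = consequence,
    af_1000g = af_1000g, af_esp = af_esp, af_exac = af_exac,
    calls = list(tibble::tibble(
      sample_id = sprintf("S%02d", seq_len(n_samples)),
      genotype = gt, depth = as.numeric(dp)))
  )
}

make_variants <- function(...) {
  out <- dplyr::bind_rows(...)
  attr(out, "freq_cols") <- FREQ_COLS
  out
}

# regions for filter tests: capture chr1:[0, 10000), masks inside it
test_regions <- function() {
  list(capture = region_set("chr1", 0, 10000, name = "capture"),
       tandem_repeat = region_set("chr1", 5000, 5200, name = "tandem_repeat"),
       segdup = region_set("chr1", 6000, 6200, name = "segdup"))
}

write_mini_vcf <- function(lines, path = tempfile(fileext = ".vcf"),
                           samples = c("S01", "S02")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000000>",
    "##INFO=<ID=Func.refGene,Number=1,Type=String,Description=\"f\">",
    "##INFO=<ID=ExonicFunc.refGene,Number=1,Type=String,Description=\"e\">",
    "##INFO=<ID=1000g2015aug_all,Number=1,Type=Float,Description=\"g\">",
    "##INFO=<ID=esp6500siv2_all,Number=1,Type=Float,Description=\"s\">",
    "##INFO=<ID=ExAC_nontcga_ALL,Number=1,Type=Float,Description=\"x\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, lines), path)
  path
}

tiny_scenario <- function(seed = 7) {
  scenario_config(
    populations = tibble::tibble(
      label = c("A", "B"), n_samples = c(10, 8),
      exome_rate = c(2e-6, 3e-6), panel_enrichment = c(5, 1)),
    exome_size = 2e6, panel_size = 4e4, n_blocks = 40, seed = seed)
}

tiny_run_config <- function(sim, ...) {
  run_config(cohort = "tiny", vcf = sim$paths$vcf,
             coverage = dirname(sim$paths$coverage[[1]]),
             capture = sim$paths$capture, panel = sim$paths$panel,
             masks = c(tandem_repeat = sim$paths$tandem_repeat,
                       segdup = sim$paths$segdup),
             ccds = sim$paths$ccds,
             populations = sim$paths$populations, ...)
}

# independent oracles -------------------------------------------------------

# two-sided Poisson p by explicit pmf summation with tail mass < 1e-12
poisson_oracle <- function(x, mu) {
  if (mu == 0) return(if (x == 0) 1 else 0)
  kmax <- max(x, ceiling(mu + 20 * sqrt(mu) + 50))
  while (ppois(kmax, mu, lower.tail = FALSE) > 1e-12) kmax <- kmax * 2
  probs <- dpois(0:kmax, mu)
  min(1, sum(probs[probs <= dpois(x, mu) * (1 + 1e-7)]))
}

# two-sided Fisher p by full enumeration of tables with fixed margins,
# probabilities from lchoose only
fisher_oracle <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; N <- r1 + r2
  k <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(N, c1)
  p <- exp(logp)
  pobs <- exp(lchoose(r1, a) + lchoose(r2, c_) - lchoose(N, c1))
  min(1, sum(p[p <= pobs * (1 + 1e-7)]))
}

# two-sided Mann-Whitney p by full permutation enumeration of the midrank sum
mw_oracle <- function(a, b) {
  n1 <- length(a); N <- n1 + length(b)
  ranks <- rank(c(a, b))
  w_obs <- sum(ranks[seq_len(n1)])
  mu_w <- n1 * (N + 1) / 2
  sets <- utils::combn(N, n1)
  w_all <- colSums(matrix(ranks[sets], nrow = n1))
  mean(abs(w_all - mu_w) >= abs(w_obs - mu_w) - 1e-9)
}
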
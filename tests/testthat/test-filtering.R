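test_that("low-depth genotypes become missing and high-missingness sites drop", {
  cfg <- filter_config()
  # 2/10 calls at depth 2 -> missing rate 0.2 > 0.1 -> removed
  v1 <- make_variants(make_variant(100, genotypes = c("het", "hom_ref"),
                                   depths = c(2, 2)))
  expect_equal(nrow(apply_genotype_missingness(v1, cfg)), 0)
  # 1/10 at depth 2 -> rate 0.1, not strictly above threshold -> retained
  v2 <- make_variants(make_variant(100, genotypes = "het", depths = 2))
  kept <- apply_genotype_missingness(v2, cfg)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$calls[[1]]$genotype[1], "missing")
  # all depths adequate -> calls unchanged
  v3 <- make_variants(make_variant(100))
  expect_equal(apply_genotype_missingness(v3, cfg)$calls[[1]],
               v3$calls[[1]])
  # zero samples is a contract violation
  v0 <- v3
  v0$calls[[1]] <- v0$calls[[1]][0, ]
  expect_error(apply_genotype_missingness(v0, cfg), "zero samples")
})

test_that("only protein-truncating classes are retained", {
  cfg <- filter_config()
  expect_true(classify_truncating("stopgain", cfg))
  expect_true(classify_truncating("splice_site", cfg))
  expect_true(classify_truncating("frameshift_indel", cfg))
  expect_true(classify_truncating("stoploss", cfg))
  expect_false(classify_truncating("other", cfg))
})

test_that("frequency filter removes only variants known to be common", {
  cfg <- filter_config()
  v <- make_variants(
    make_variant(100, af_1000g = 0.05),
    make_variant(200, af_1000g = 0.001, af_exac = 0.015),
    make_variant(300),                    # unknown everywhere -> retained
    make_variant(400, af_esp = 0.02))     # exactly at the cutoff -> retained
  expect_equal(apply_maf_filter(v, cfg), c(FALSE, TRUE, TRUE, TRUE))
  bad <- make_variants(make_variant(500, af_1000g = 1.5))
  expect_error(apply_maf_filter(bad, cfg), "outside")
})

test_that("structural filters apply strict printed thresholds", {
  cfg <- filter_config()
  regions <- test_regions()
  v <- make_variants(
    make_variant(101, consequence = "frameshift_indel",
                 alt = paste(rep("A", 22), collapse = "")),  # 21 bp ins
    make_variant(201, consequence = "frameshift_indel",
                 alt = paste(rep("A", 21), collapse = "")),  # 20 bp ins
    make_variant(301, genotypes = "het", depths = 14),
    make_variant(401, genotypes = "het", depths = 15),
    make_variant(6101),                                      # in segdup
    make_variant(5101),                                      # in tandem rep
    make_variant(20001))                                     # outside capture
  rb <- apply_structural_filters(v, cfg, regions)
  expect_equal(rb, c("long_indel", NA, "carrier_depth", NA, "masked_region",
                     "masked_region", "outside_restriction"))
})

test_that("the carrier-depth rule is per-event, not per-site", {
  cfg <- filter_config()
  regions <- test_regions()
  # two carriers: one at depth 14 (event lost), one at 40 (event kept)
  v <- make_variants(make_variant(150, genotypes = c("het", "het"),
                                  depths = c(14, 40)))
  res <- run_filter_cascade(v, cfg, regions)
  expect_equal(nrow(res$variants), 1)
  expect_equal(nrow(res$events), 1)
  expect_equal(res$events$sample_id, "S02")
  expect_equal(res$events$depth, 40)
})

test_that("cascade accounting is exact and dispositions unique", {
  cfg <- filter_config()
  regions <- test_regions()
  v <- make_variants(
    make_variant(100),                                     # survives
    make_variant(200, genotypes = c("het", "het"), depths = c(2, 2)),
    make_variant(300, consequence = "other"),
    make_variant(400, af_1000g = 0.10),
    make_variant(500, consequence = "frameshift_indel",
                 alt = paste(rep("G", 26), collapse = "")),
    make_variant(600, genotypes = "het", depths = 10),
    make_variant(5100),
    make_variant(20005))
  res <- run_filter_cascade(v, cfg, regions)
  rep_tbl <- res$report
  # chain: input of each filter is the survivors of the previous
  expect_equal(rep_tbl$n_input[-1], rep_tbl$n_surviving[-nrow(rep_tbl)])
  # conservation: removals plus final survivors account for every input
  expect_equal(sum(rep_tbl$n_removed) + rep_tbl$n_surviving[nrow(rep_tbl)],
               rep_tbl$n_input[1])
  expect_equal(rep_tbl$n_removed, c(1, 1, 1, 1, 1, 1, 1))
  # exactly one removing filter recorded per removed variant
  disp <- res$dispositions
  expect_equal(sum(is.na(disp$removed_by)), 1)
  expect_setequal(
    disp$removed_by[!is.na(disp$removed_by)],
    c("genotype_missingness", "truncating_class", "allele_frequency",
      "long_indel", "carrier_depth", "masked_region", "outside_restriction"))
  expect_error(run_filter_cascade(v, cfg, regions["capture"]),
               "not supplied")
})

test_that("cascade is idempotent", {
  cfg <- filter_config()
  regions <- test_regions()
  v <- make_variants(make_variant(100), make_variant(200, af_1000g = 0.5),
                     make_variant(700, genotypes = "het", depths = 2))
  once <- run_filter_cascade(v, cfg, regions)
  twice <- run_filter_cascade(once$variants, cfg, regions)
  expect_equal(as.data.frame(twice$variants[, 1:6]),
               as.data.frame(once$variants[, 1:6]))
  expect_equal(twice$events, once$events)
})

test_that("neutralizing every filter returns the input unchanged", {
  cfg <- filter_config(genotype_depth_min = 0, site_missing_rate_max = 1,
                       maf_max = 1, indel_length_max = 1e9,
                       variant_depth_min = 0,
                       truncating_classes = c(truncating_classes(), "other"),
                       masks = character(0), restrict_to = character(0))
  v <- make_variants(
    make_variant(100, consequence = "other", af_1000g = 0.9),
    make_variant(5100, genotypes = "het", depths = 1),
    make_variant(20005, consequence = "frameshift_indel",
                 alt = paste(rep("T", 40), collapse = "")))
  res <- run_filter_cascade(v, cfg, regions = list())
  expect_equal(nrow(res$variants), 3)
  expect_equal(res$report$n_removed, rep(0, 7))
  expect_equal(as.data.frame(res$variants[, 1:6]), as.data.frame(v[, 1:6]))
})

test_that("a long frameshift indel is truncating by class yet length-filtered", {
  cfg <- filter_config()
  regions <- test_regions()
  v <- make_variants(make_variant(100, consequence = "frameshift_indel",
                                  alt = paste(rep("A", 26), collapse = "")))
  expect_true(classify_truncating(v$consequence, cfg))
  res <- run_filter_cascade(v, cfg, regions)
  expect_equal(res$dispositions$removed_by, "long_indel")
})
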
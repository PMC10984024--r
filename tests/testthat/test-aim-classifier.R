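test_that("DAF tiers and the genotyping-success filter follow the published thresholds", {
  # build genotypes: cohorts of 10 + 10 samples, 4 sites
  rows <- list(
    c(rep("1/1", 10), rep("0/0", 10)),                    # fixed difference
    c(rep("1/1", 9), "0/1", rep("0/0", 9), "0/1"),        # |dAF| = 0.90
    c(rep("1/1", 10), rep("0/0", 9), "0/1"),              # |dAF| = 0.95
    c("1/1", rep("./.", 19))                              # success 1/20 < 10%
  )
  g <- toy_geno(rows)
  meta <- tibble::tibble(sample_id = g$samples,
                         cohort = rep(c("A", "B"), each = 10))
  daf <- compute_daf(g, meta, "A", "B")
  expect_equal(nrow(daf), 3)  # low-success site excluded
  expect_equal(daf$tier, c("fixed", "ge85", "ge85"))
  expect_equal(daf$daf[2], 0.90)
})

test_that("panels nest by tier and realise the published 3/6/201 composition on a matched fixture", {
  # constructed DAF table with 3 fixed, 3 at >98% and 195 more above 85%
  daf <- tibble::tibble(
    contig = "2R", pos = seq_len(201), ref = "A", alt = "T",
    freq_a = c(rep(1, 3), rep(0.995, 3), rep(0.95, 195)),
    freq_b = c(rep(0, 3), rep(0.005, 3), rep(0.05, 195)),
    success = 1
  ) %>%
    dplyr::mutate(daf = abs(freq_a - freq_b),
                  tier = dplyr::case_when(daf >= 1 - 1e-12 ~ "fixed",
                                          daf > 0.98 ~ "ge98",
                                          daf > 0.85 ~ "ge85",
                                          TRUE ~ "none"))
  expect_equal(nrow(build_panel(daf, "fixed")), 3)
  expect_equal(nrow(build_panel(daf, "ge98")), 6)
  expect_equal(nrow(build_panel(daf, "ge85")), 201)
})

test_that("markers are oriented toward the allele commoner in the focal cohort", {
  daf <- tibble::tibble(
    contig = "2R", pos = 1:2, ref = "A", alt = "T",
    freq_a = c(0.95, 0.05), freq_b = c(0.05, 0.95),
    success = 1, daf = 0.9, tier = "ge85"
  )
  panel <- build_panel(daf, "ge85")
  expect_equal(panel$a_allele, c("T", "A"))  # alt commoner in A at site 1
})

test_that("allelic percentage matches direct arithmetic and ignores uncalled markers", {
  # 201 markers: 180 homozygous-A, 21 homozygous-B -> 100 * 360/402
  gt <- c(rep("1/1", 180), rep("0/0", 21))
  g <- toy_geno(as.list(gt), pos = seq_len(201))
  panel <- tibble::tibble(contig = "3R", pos = seq_len(201),
                          a_allele = "T", b_allele = "A")
  ap <- allelic_percentage(g, panel)
  expect_equal(ap$allelic_percentage, 100 * 360 / 402, tolerance = 1e-9)
  # homozygous A everywhere -> 100; heterozygous everywhere -> 50
  g100 <- toy_geno(as.list(rep("1/1", 201)), pos = seq_len(201))
  expect_equal(allelic_percentage(g100, panel)$allelic_percentage, 100)
  g50 <- toy_geno(as.list(rep("0/1", 201)), pos = seq_len(201))
  expect_equal(allelic_percentage(g50, panel)$allelic_percentage, 50)
  # adding markers where the sample is uncalled leaves the value unchanged
  gmix <- toy_geno(as.list(c(gt, rep("./.", 9))), pos = seq_len(210))
  panel210 <- tibble::tibble(contig = "3R", pos = seq_len(210),
                             a_allele = "T", b_allele = "A")
  expect_equal(allelic_percentage(gmix, panel210)$allelic_percentage,
               100 * 360 / 402, tolerance = 1e-9)
})

test_that("classification applies strict 80/20 cut-offs", {
  ap <- tibble::tibble(
    sample_id = c("hi", "mid", "lo", "none"),
    allelic_percentage = c(85, 50, 15, NA),
    n_called_markers = c(10L, 10L, 10L, 0L),
    n_missing_markers = c(0L, 0L, 0L, 10L)
  )
  rep <- classify_samples(ap)
  lab <- stats::setNames(rep$samples$label, rep$samples$sample_id)
  expect_equal(lab[["hi"]], "taxon-A")
  expect_equal(lab[["mid"]], "unassigned")
  expect_equal(lab[["lo"]], "taxon-B")
  expect_equal(lab[["none"]], "unassigned")
  expect_error(classify_samples(ap, hi_cutoff = 20, lo_cutoff = 80), "exceed")
})

test_that("panel discovery separates the discovery cohorts completely given a fixed difference", {
  sc <- simulate_three_taxa(n_variants = 4000, cohort_size = 25, seed = 61,
                            admixed_alpha = NULL, outgroup_drift = NULL)
  g <- geno_subset(sc$geno, variants = filter_sites(sc$geno, 0.01))
  daf <- compute_daf(g, sc$meta, "BIS", "GA")
  panel <- build_panel(daf, "ge85")
  expect_gt(nrow(panel), 0)
  ap <- allelic_percentage(g, panel)
  rep <- classify_samples(ap, truth = sc$meta,
                          taxon_a_label = "BIS", taxon_b_label = "GA")
  expect_equal(attr(rep$accuracy, "overall"), 1)
})

test_that("held-out and admixed individuals behave like the published bands", {
  sc <- simulate_three_taxa(n_variants = 20000, cohort_size = 50, seed = 62,
                            admixed_alpha = NULL, outgroup_drift = NULL)
  g <- geno_subset(sc$geno, variants = filter_sites(sc$geno, 0.01))
  daf <- compute_daf(g, sc$meta, "BIS", "GA")
  panel <- build_panel(daf, "ge85")
  expect_gte(nrow(panel), 50)
  key <- paste(g$variants$contig, g$variants$pos)
  subset_to <- function(gh) {
    geno_subset(gh, variants = match(key, paste(gh$variants$contig,
                                                gh$variants$pos)))
  }
  # held-out draws from the same population frequencies
  hb <- subset_to(simulate_genotypes(sc$freqs$BIS, 50, 63, sample_prefix = "HB"))
  hg <- subset_to(simulate_genotypes(sc$freqs$GA, 50, 64, sample_prefix = "HG"))
  apb <- allelic_percentage(hb, panel)
  apg <- allelic_percentage(hg, panel)
  acc <- (sum(apb$allelic_percentage > 80) + sum(apg$allelic_percentage < 20)) / 100
  expect_gte(acc, 0.99)
  # 50/50 admixed individuals sit near 50% (within +/- 10)
  fadm <- simulate_admixed(sc$freqs$BIS, sc$freqs$GA, 0.5)
  ha <- subset_to(simulate_genotypes(fadm, 30, 65, sample_prefix = "HA"))
  apa <- allelic_percentage(ha, panel)
  expect_true(all(abs(apa$allelic_percentage - 50) <= 10))
})
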
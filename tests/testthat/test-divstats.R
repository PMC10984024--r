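test_that("windowed pi matches combinatorial oracles", {
  w <- tibble::tibble(contig = "3R", start = 1L, end = 1000L,
                      n_accessible = 1000L)
  # site (2 ref, 8 alt), n = 10 -> 16/45 per site
  ac <- toy_ac(2, 8)
  out <- diversity_windows(ac, w)
  expect_equal(out$pi_per_base, (16 / 45) / 1000)
  # site (5, 5): (25/45)/1000
  expect_equal(diversity_windows(toy_ac(5, 5), w)$pi_per_base,
               (25 / 45) / 1000, tolerance = 1e-12)
  # monomorphic window -> 0
  expect_equal(diversity_windows(toy_ac(10, 0), w)$pi_per_base, 0)
})

test_that("pi from allele counts equals brute-force pairwise haplotype differences", {
  set.seed(31)
  n_hap <- 20
  L <- 200
  haps <- matrix(rbinom(L * n_hap, 1, runif(L, 0.1, 0.9)), nrow = L)
  # brute force: mean pairwise difference per site summed over sites
  brute <- 0
  for (i in 1:(n_hap - 1)) for (j in (i + 1):n_hap) {
    brute <- brute + sum(haps[, i] != haps[, j])
  }
  brute <- brute / choose(n_hap, 2)
  ac <- toy_ac(n_hap - rowSums(haps), rowSums(haps))
  w <- tibble::tibble(contig = "3R", start = 1L, end = 200L,
                      n_accessible = 1L)  # denominator 1: window sum only
  expect_equal(diversity_windows(ac, w)$pi_per_base, brute, tolerance = 1e-12)
})

test_that("Tajima's D is undefined without segregation and signs rare-variant excess", {
  w <- tibble::tibble(contig = "3R", start = 1L, end = 10000L,
                      n_accessible = 10000L)
  expect_true(is.na(diversity_windows(toy_ac(rep(20, 3), rep(0, 3)), w)$tajima_d))
  # all singletons, n = 20, S = 10 -> D < 0 (pi_sum < S/a1)
  ac_singletons <- toy_ac(rep(19, 10), rep(1, 10))
  expect_lt(diversity_windows(ac_singletons, w)$tajima_d, 0)
  # neutral constant-size coalescent-free check: balanced frequencies give
  # D near zero on average (simulation oracle at small scale)
  set.seed(32)
  ds <- replicate(200, {
    # sample allele counts from the neutral SFS: P(i) proportional to 1/i
    n <- 20
    probs <- (1 / (1:(n - 1)))
    counts <- sample(1:(n - 1), 10, replace = TRUE, prob = probs)
    diversity_windows(toy_ac(n - counts, counts), w)$tajima_d
  })
  expect_gt(mean(ds), -0.3)
  expect_lt(mean(ds), 0.3)
})

test_that("Hudson FST matches the hand-computed Bhatia example and fixed-difference anchors", {
  # pop1 8/10 alt, pop2 2/10 alt
  f <- hudson_fst(toy_ac(2, 8), toy_ac(8, 2))
  expect_equal(f$genome_wide, (0.36 - 0.16 / 9 - 0.16 / 9) / 0.68,
               tolerance = 1e-9)
  expect_equal(f$genome_wide, 0.4771242, tolerance = 1e-6)
  # fixed difference -> FST = 1
  expect_equal(hudson_fst(toy_ac(0, 100), toy_ac(100, 0))$genome_wide, 1)
  # identical cohorts at many sites -> near zero (unbiasedness)
  set.seed(33)
  p <- runif(10000, 0.1, 0.9)
  ac1 <- simulate_allele_counts(p, 50, seed = 34)
  ac2 <- simulate_allele_counts(p, 50, seed = 35)
  self <- hudson_fst(ac1, ac2)$genome_wide
  expect_gt(self, -0.01)
  expect_lt(self, 0.01)
})

test_that("FST and Dxy are symmetric and windowed values are ratios of sums", {
  set.seed(36)
  p <- runif(500, 0.1, 0.9)
  k <- (1 - 0.05) / 0.05
  ac1 <- simulate_allele_counts(rbeta(500, p * k, (1 - p) * k), 40, seed = 37)
  ac2 <- simulate_allele_counts(rbeta(500, p * k, (1 - p) * k), 40, seed = 38)
  expect_equal(hudson_fst(ac1, ac2)$genome_wide,
               hudson_fst(ac2, ac1)$genome_wide)
  w <- tibble::tibble(contig = "3R", start = c(1L, 251L),
                      end = c(250L, 500L), n_accessible = c(250L, 250L))
  d12 <- dxy_windows(ac1, ac2, w)
  d21 <- dxy_windows(ac2, ac1, w)
  expect_equal(d12$dxy_per_base, d21$dxy_per_base)
  # ratio of sums, not mean of ratios
  f <- hudson_fst(ac1, ac2, w)
  ps <- f$per_site[1:250, ]
  expect_equal(f$windows$fst[1], sum(ps$num) / sum(ps$den))
})

test_that("Dxy matches direct per-site formulas", {
  # p1 = 1, p2 = 0 over 100 accessible bases -> 0.01
  w <- tibble::tibble(contig = "3R", start = 1L, end = 100L,
                      n_accessible = 100L)
  expect_equal(dxy_windows(toy_ac(0, 10), toy_ac(10, 0), w)$dxy_per_base, 0.01)
  # p1 = 0.8, p2 = 0.2 -> per-site 0.68
  expect_equal(dxy_windows(toy_ac(2, 8), toy_ac(8, 2), w)$dxy_per_base,
               0.68 / 100)
  # identical monomorphic cohorts -> 0
  expect_equal(dxy_windows(toy_ac(10, 0), toy_ac(10, 0), w)$dxy_per_base, 0)
})

test_that("folded SFS folds symmetric counts and excludes monomorphic sites", {
  ac <- toy_ac(c(9, 9, 1, 10, 0), c(1, 1, 9, 0, 10))
  sfs <- folded_sfs(ac)
  expect_equal(sfs$n_sites[1], 3L)  # counts 1, 1 and 9 (folds to 1)
  expect_equal(sum(sfs$n_sites), 3L)
  expect_equal(attr(sfs, "n_used"), 3L)
  expect_equal(nrow(sfs), 5L)  # bins 1..floor(10/2)
})

test_that("population expansion inflates the singleton fraction relative to constant size", {
  set.seed(39)
  n <- 40
  # constant size: counts from the 1/i neutral spectrum; expansion: excess
  # of singletons (star-like genealogy pushes mass to i = 1)
  const_counts <- sample(1:(n - 1), 4000, replace = TRUE, prob = 1 / (1:(n - 1)))
  exp_counts <- sample(1:(n - 1), 4000, replace = TRUE,
                       prob = c(8, rep(1, n - 2)) / (1:(n - 1)))
  sfs_c <- folded_sfs(toy_ac(n - const_counts, const_counts))
  sfs_e <- folded_sfs(toy_ac(n - exp_counts, exp_counts))
  singleton_frac <- function(s) s$n_sites[1] / sum(s$n_sites)
  expect_gt(singleton_frac(sfs_e), singleton_frac(sfs_c))
})

test_that("top-window ranking annotates inclusive gene overlaps", {
  w <- tibble::tibble(
    contig = "3R", start = c(1L, 100001L, 200001L),
    end = c(100000L, 200000L, 300000L), n_accessible = 100000L,
    fst = c(0.5, 0.1, 0.3)
  )
  genes <- tibble::tibble(
    gene_id = c("g_in", "g_boundary", "g_out"),
    contig = "3R",
    start = c(10000L, 150000L, 400000L),
    end = c(20000L, 200001L, 410000L),
    strand = "+"
  )
  top <- rank_top_windows(w, genes, "fst", k = 2)
  expect_equal(top$start, c(1L, 200001L))
  expect_true("g_in" %in% top$genes[[1]])
  # gene ending exactly at a window start is listed (inclusive overlap)
  expect_true("g_boundary" %in% top$genes[[2]])
  expect_false("g_out" %in% unlist(top$genes))
  # k larger than window count returns everything
  expect_equal(nrow(rank_top_windows(w, genes, "fst", k = 10)), 3)
})
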
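#' Delete-one-block jackknife over a ratio of sums
#'
#' The point estimate is the all-blocks ratio `sum(num) / sum(den)`; the
#' standard error is the delete-one-block jackknife
#' `SE^2 = (m - 1) / m * sum_j (R_{-j} - mean(R_{-.}))^2` with `R_{-j}` the
#' ratio after removing block `j`. `Z = estimate / SE`; when the blocks are
#' identical the SE is zero and Z is returned as `NA`.
#'
#' @param num_blocks,den_blocks per-block numerator and denominator sums.
#' @return Tibble with `estimate`, `se`, `z`, `n_blocks`.
#' @export
block_jackknife <- function(num_blocks, den_blocks) {
  stopifnot(length(num_blocks) == length(den_blocks))
  m <- length(num_blocks)
  if (m < 2) abort("need at least two blocks for a jackknife SE")
  tot_n <- sum(num_blocks)
  tot_d <- sum(den_blocks)
  est <- tot_n / tot_d
  loo <- (tot_n - num_blocks) / (tot_d - den_blocks)
  se <- sqrt((m - 1) / m * sum((loo - mean(loo))^2))
  tibble(
    estimate = est,
    se = se,
    z = if (se > 0) est / se else NA_real_,
    n_blocks = m
  )
}

# assign site indices to contiguous SNP blocks of block_size sites
snp_blocks <- function(n_sites, block_size) {
  ((seq_len(n_sites) - 1L) %/% as.integer(block_size)) + 1L
}

# shared skeleton: per-site num/den -> blocked jackknife tibble
blockwise_ratio <- function(num, den, ok, block_size) {
  use <- ok & is.finite(num) & is.finite(den)
  idx <- which(use)
  if (length(idx) < 2) abort("too few informative sites")
  blk <- snp_blocks(length(idx), block_size)
  nb <- tapply(num[idx], blk, sum)
  db <- tapply(den[idx], blk, sum)
  if (length(nb) < 2) {
    # single block: report the point estimate with NA significance
    return(tibble(estimate = sum(nb) / sum(db), se = NA_real_, z = NA_real_,
                  n_blocks = 1L) %>% mutate(n_sites = length(idx)))
  }
  block_jackknife(as.numeric(nb), as.numeric(db)) %>%
    mutate(n_sites = length(idx))
}

#' Three-population f3 statistic with block-jackknife significance
#'
#' Tests whether target cohort X is admixed between sources A and B. The
#' per-site numerator is `(x - a)(x - b) - x(1 - x)/(n_x - 1)` (the last
#' term corrects for sampling noise in the target frequency) and the
#' heterozygosity-scaled denominator is `2 x (1 - x) n_x / (n_x - 1)`.
#' The estimate is the ratio of sums over all informative sites; a
#' significantly negative value (`z < -5` by convention here) indicates
#' the target carries ancestry from both sources. The unnormalised f3
#' (ratio with denominator 1 per site) is also reported, since only the
#' sign and Z enter the admixture test.
#'
#' @param acX,acA,acB allele-count tibbles (target, source A, source B)
#'   aligned on the same variants.
#' @param block_size_snps jackknife block size in SNPs.
#' @return Tibble with `statistic`, `estimate`, `estimate_raw`, `se`, `z`,
#'   `n_blocks`, `n_sites`.
#' @export
f3 <- function(acX, acA, acB, block_size_snps = 1000L) {
  stopifnot(nrow(acX) == nrow(acA), nrow(acX) == nrow(acB))
  nx <- acX$n_ref + acX$n_alt
  na <- acA$n_ref + acA$n_alt
  nb <- acB$n_ref + acB$n_alt
  x <- acX$n_alt / nx
  a <- acA$n_alt / na
  b <- acB$n_alt / nb
  ok <- nx >= 2 & na >= 2 & nb >= 2
  num <- (x - a) * (x - b) - x * (1 - x) / (nx - 1)
  den <- 2 * x * (1 - x) * nx / (nx - 1)
  res <- blockwise_ratio(num, den, ok & den > 0, block_size_snps)
  raw <- blockwise_ratio(num, rep(1, length(num)), ok, block_size_snps)
  res %>%
    mutate(statistic = "f3", estimate_raw = raw$estimate) %>%
    select("statistic", "estimate", "estimate_raw", "se", "z",
           "n_blocks", "n_sites")
}

#' Outgroup-f3 shared-drift statistic
#'
#' The f3 estimator with the outgroup as target: larger values indicate
#' more drift shared by the test and reference cohorts since their
#' divergence from the outgroup.
#'
#' @param acTest,acRef,acOutgroup allele-count tibbles.
#' @inheritParams f3
#' @return As [f3()], with `statistic = "outgroup_f3"`.
#' @export
outgroup_f3 <- function(acTest, acRef, acOutgroup, block_size_snps = 1000L) {
  out <- f3(acOutgroup, acTest, acRef, block_size_snps)
  out$statistic <- "outgroup_f3"
  out
}

#' Patterson's D (ABBA-BABA) statistic with block-jackknife significance
#'
#' Frequency-based four-taxon test: per site,
#' `ABBA = (1 - p1) p2 p3 (1 - p4)` and `BABA = p1 (1 - p2) p3 (1 - p4)`
#' with `p4` the outgroup; `D = sum(ABBA - BABA) / sum(ABBA + BABA)`.
#' A positive D indicates an excess of derived alleles shared between
#' populations 2 and 3 (swapping P1 and P2 flips the sign exactly).
#' Polymorphic outgroup sites are retained, as the estimator is fully
#' frequency-based.
#'
#' @param ac1,ac2,ac3,ac4_outgroup allele-count tibbles for P1, P2, P3 and
#'   the outgroup, aligned on the same variants.
#' @inheritParams f3
#' @return Tibble as [f3()] with `statistic = "patterson_d"`.
#' @export
patterson_d <- function(ac1, ac2, ac3, ac4_outgroup, block_size_snps = 1000L) {
  acs <- list(ac1, ac2, ac3, ac4_outgroup)
  stopifnot(length(unique(vapply(acs, nrow, 1L))) == 1)
  p <- lapply(acs, allele_freq)
  ok <- Reduce(`&`, lapply(acs, function(a) (a$n_ref + a$n_alt) >= 2))
  abba <- (1 - p[[1]]) * p[[2]] * p[[3]] * (1 - p[[4]])
  baba <- p[[1]] * (1 - p[[2]]) * p[[3]] * (1 - p[[4]])
  den_total <- sum((abba + baba)[ok & is.finite(abba + baba)])
  if (!is.finite(den_total) || den_total == 0) {
    return(tibble(statistic = "patterson_d", estimate = NA_real_,
                  estimate_raw = NA_real_, se = NA_real_, z = NA_real_,
                  n_blocks = 0L, n_sites = sum(ok)))
  }
  res <- blockwise_ratio(abba - baba, abba + baba, ok, block_size_snps)
  res %>%
    mutate(statistic = "patterson_d", estimate_raw = .data$estimate) %>%
    select("statistic", "estimate", "estimate_raw", "se", "z",
           "n_blocks", "n_sites")
}
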
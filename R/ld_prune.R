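#' Pairwise dosage correlation (Rogers-Huff r)
#'
#' The genotype-dosage estimator of linkage disequilibrium: the Pearson
#' correlation of alternate-allele dosage vectors, computed over
#' pairwise-complete samples. Zero-variance pairs (or pairs with fewer than
#' two complete observations) are returned as `NaN`.
#'
#' @param dosages variants x samples matrix of 0/1/2 dosages with `NA`
#'   for missing genotypes.
#' @return Symmetric variants x variants matrix of r values (diagonal 1).
#' @export
rogers_huff_r <- function(dosages) {
  if (nrow(dosages) < 2) abort("need at least two variants")
  r <- suppressWarnings(cor(t(dosages), use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- NaN
  r
}

#' LD-pruning parameters
#'
#' Defaults mirror the study settings: r-squared threshold 0.01 in moving
#' windows of 500 SNPs advancing by 250.
#'
#' @param window_size_snps window width in SNPs.
#' @param step_snps window step in SNPs.
#' @param r2_threshold squared-correlation threshold in `(0, 1]`.
#' @param n_iterations number of pruning passes.
#' @return A list of validated parameters.
#' @export
prune_params <- function(window_size_snps = 500L, step_snps = 250L,
                         r2_threshold = 0.01, n_iterations = 1L) {
  if (step_snps > window_size_snps) abort("step must be <= window size")
  if (r2_threshold <= 0 || r2_threshold > 1) abort("r2 threshold must be in (0, 1]")
  list(window_size_snps = as.integer(window_size_snps),
       step_snps = as.integer(step_snps),
       r2_threshold = r2_threshold,
       n_iterations = as.integer(n_iterations))
}

#' Locate variants unlinked below an r-squared threshold
#'
#' Greedy forward scan: within each moving window, every pair of still-kept
#' variants with squared dosage correlation above the threshold drops the
#' *later* variant; windows advance by `step_snps`. Deterministic for a
#' fixed input order. Pairs whose correlation is undefined (zero variance
#' or fewer than two pairwise-complete samples) are treated as unlinked.
#'
#' @param dosages variants x samples dosage matrix (position-ordered rows).
#' @param params parameter list from [prune_params()].
#' @return Logical keep-mask over variants.
#' @export
locate_unlinked <- function(dosages, params = prune_params()) {
  L <- nrow(dosages)
  keep <- rep(TRUE, L)
  if (L < 2) return(keep)
  for (iter in seq_len(params$n_iterations)) {
    changed <- FALSE
    starts <- seq(1L, max(1L, L), by = params$step_snps)
    for (s in starts) {
      e <- min(s + params$window_size_snps - 1L, L)
      if (e <= s) next
      idx <- s:e
      live <- idx[keep[idx]]
      if (length(live) < 2) next
      r <- suppressWarnings(cor(t(dosages[live, , drop = FALSE]),
                                use = "pairwise.complete.obs"))
      r2 <- r^2
      r2[!is.finite(r2)] <- 0
      for (a in seq_along(live)) {
        if (!keep[live[a]]) next
        hits <- which(r2[a, ] > params$r2_threshold)
        hits <- hits[hits > a & keep[live[hits]]]
        if (length(hits)) {
          keep[live[hits]] <- FALSE
          changed <- TRUE
        }
      }
      if (e >= L) break
    }
    if (!changed) break
  }
  keep
}
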
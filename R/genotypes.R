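#' Genotype container
#'
#' A `geno` object bundles the three pieces every SNP statistic needs:
#' a variant table, a diploid call array, and the sample identifiers.
#' Calls are stored as a variants x samples x 2 integer array with values
#' 0 (reference allele), 1 (alternate allele) or `NA` (missing). Half-called
#' genotypes (one allele missing) are normalised to fully missing at
#' construction time, so a genotype is either fully called or fully `NA`.
#'
#' Coordinates are 1-based inclusive throughout the package; BED input is
#' converted from 0-based half-open on read.
#'
#' @param calls integer array, variants x samples x 2, values in {0, 1, NA}.
#' @param variants tibble with columns `contig`, `pos`, `ref`, `alt` and
#'   optionally `pass_site_filter` (defaults to `TRUE`).
#' @param samples character vector of unique sample identifiers, one per
#'   column of `calls`.
#' @return An object of class `geno`.
#' @export
new_geno <- function(calls, variants, samples) {
  variants <- as_tibble(variants)
  if (!all(c("contig", "pos", "ref", "alt") %in% names(variants))) {
    abort("`variants` needs columns contig, pos, ref, alt")
  }
  if (!"pass_site_filter" %in% names(variants)) {
    variants$pass_site_filter <- TRUE
  }
  if (length(dim(calls)) != 3L || dim(calls)[3] != 2L) {
    abort("`calls` must be a variants x samples x 2 array")
  }
  if (dim(calls)[1] != nrow(variants)) {
    abort("`calls` and `variants` disagree on the number of variants")
  }
  if (dim(calls)[2] != length(samples)) {
    abort("`calls` and `samples` disagree on the number of samples")
  }
  if (anyDuplicated(samples)) abort("sample ids must be unique")
  storage.mode(calls) <- "integer"
  # half-calls -> fully missing
  half <- xor(is.na(calls[, , 1, drop = FALSE]), is.na(calls[, , 2, drop = FALSE]))
  if (any(half)) {
    idx <- which(half[, , 1], arr.ind = TRUE)
    calls[cbind(idx, 1L)] <- NA_integer_
    calls[cbind(idx, 2L)] <- NA_integer_
  }
  # positions strictly increasing within each contig
  ord_ok <- variants %>%
    group_by(.data$contig) %>%
    summarise(ok = all(diff(.data$pos) > 0) || n() == 1L) %>%
    pull(.data$ok)
  if (!all(ord_ok)) abort("positions must be strictly increasing within a contig")
  structure(
    list(calls = calls, variants = variants, samples = as.character(samples)),
    class = "geno"
  )
}

#' @export
print.geno <- function(x, ...) {
  cat(sprintf(
    "<geno> %d variants x %d samples (%s)\n",
    n_variants(x), length(x$samples),
    paste(unique(x$variants$contig), collapse = ", ")
  ))
  invisible(x)
}

#' @rdname new_geno
#' @param g a `geno` object.
#' @export
n_variants <- function(g) nrow(g$variants)

#' Subset a genotype container by variant index and/or sample id
#'
#' @param g a `geno` object.
#' @param variants integer or logical index into the variant rows.
#' @param samples character vector of sample ids or index into samples.
#' @return A `geno` object.
#' @export
geno_subset <- function(g, variants = NULL, samples = NULL) {
  vi <- if (is.null(variants)) seq_len(n_variants(g)) else variants
  if (is.logical(vi)) vi <- which(vi)
  si <- if (is.null(samples)) seq_along(g$samples) else samples
  if (is.character(si)) {
    miss <- setdiff(si, g$samples)
    if (length(miss)) abort(paste0("unknown sample id(s): ", paste(miss, collapse = ", ")))
    si <- match(si, g$samples)
  }
  new_geno(
    g$calls[vi, si, , drop = FALSE],
    g$variants[vi, , drop = FALSE],
    g$samples[si]
  )
}

#' Allele dosage matrix
#'
#' Counts of the alternate allele per genotype: a variants x samples integer
#' matrix with values 0, 1, 2 or `NA` for missing genotypes.
#'
#' @param g a `geno` object.
#' @return Integer matrix, variants x samples, dimnames carrying sample ids.
#' @export
geno_dosage <- function(g) {
  d <- g$calls[, , 1, drop = FALSE][, , 1] + g$calls[, , 2, drop = FALSE][, , 1]
  d <- matrix(d, nrow = n_variants(g), ncol = length(g$samples))
  colnames(d) <- g$samples
  d
}

#' Per-cohort allele counts
#'
#' Tallies called reference and alternate alleles per variant over a subset
#' of samples. Missing alleles are excluded, so `n_ref + n_alt` is at most
#' twice the subset size at every variant.
#'
#' @param g a `geno` object.
#' @param sample_subset character vector of sample ids (default: all).
#' @return A tibble with columns `contig`, `pos`, `n_ref`, `n_alt` and
#'   `uninformative` (TRUE where no allele was called at all).
#' @export
allele_counts <- function(g, sample_subset = NULL) {
  if (!is.null(sample_subset) && length(sample_subset) == 0L) {
    abort("`sample_subset` must be non-empty")
  }
  gs <- if (is.null(sample_subset)) g else geno_subset(g, samples = sample_subset)
  a <- gs$calls
  n_alt <- rowSums(a == 1L, dims = 1, na.rm = TRUE)
  n_called <- rowSums(!is.na(a), dims = 1)
  tibble(
    contig = gs$variants$contig,
    pos = gs$variants$pos,
    n_ref = as.integer(n_called - n_alt),
    n_alt = as.integer(n_alt),
    uninformative = n_called == 0L
  )
}

#' Alternate-allele frequency from allele counts
#'
#' @param ac allele-count tibble from [allele_counts()].
#' @return Numeric vector of alt-allele frequencies (`NaN` where uncalled).
#' @export
allele_freq <- function(ac) {
  ac$n_alt / (ac$n_ref + ac$n_alt)
}

#' Site filtering by biallelism, site-filter mask and minor allele frequency
#'
#' Retains variants that (optionally) pass the upstream site-filter mask,
#' are biallelic SNPs, and have minor allele frequency at least `maf_min`
#' computed over all non-missing alleles in the whole sample set (global
#' MAF). The threshold is inclusive. Monomorphic variants never pass.
#'
#' @param g a `geno` object.
#' @param maf_min minor allele frequency threshold in `[0, 0.5]`.
#' @param require_biallelic drop variants whose ref/alt are not single
#'   nucleotides or are identical.
#' @param require_pass drop variants failing `pass_site_filter`.
#' @return Sorted integer vector of retained variant indices.
#' @export
filter_sites <- function(g, maf_min = 0.01, require_biallelic = TRUE,
                         require_pass = TRUE) {
  if (maf_min < 0 || maf_min > 0.5) abort("`maf_min` must be in [0, 0.5]")
  ac <- allele_counts(g)
  n <- ac$n_ref + ac$n_alt
  p <- ifelse(n > 0, ac$n_alt / n, NA_real_)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf >= maf_min & maf > 0
  if (require_pass) keep <- keep & g$variants$pass_site_filter
  if (require_biallelic) {
    keep <- keep &
      nchar(g$variants$ref) == 1L & nchar(g$variants$alt) == 1L &
      g$variants$ref != g$variants$alt & !grepl(",", g$variants$alt, fixed = TRUE)
  }
  out <- which(keep)
  if (length(out) == 0L) warn("no variants retained by filter_sites()")
  out
}

#' Random down-sampling of variant indices
#'
#' Reproducible uniform down-sampling to at most `n` variants; the result is
#' sorted so downstream window logic sees position-ordered variants.
#'
#' @param indices integer vector of candidate variant indices.
#' @param n maximum number to keep.
#' @param seed integer seed for the draw.
#' @return Sorted integer vector of length `min(n, length(indices))`.
#' @export
downsample_variants <- function(indices, n, seed) {
  if (n < 1) abort("`n` must be >= 1")
  if (length(indices) <= n) return(sort(indices))
  withr_seed(seed)
  sort(sample(indices, n))
}

# local seed scoping without depending on withr at run time
withr_seed <- function(seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  invisible(NULL)
}
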
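# Small constructors used across test files.

# geno object from a list of per-sample genotype strings like "0/1";
# one character vector per variant.
toy_geno <- function(gt_rows, contig = "3R", pos = NULL, ref = "A", alt = "T") {
  L <- length(gt_rows)
  N <- length(gt_rows[[1]])
  calls <- array(NA_integer_, dim = c(L, N, 2))
  for (i in seq_len(L)) {
    parts <- strsplit(gt_rows[[i]], "/", fixed = TRUE)
    a1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1)))
    a2 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2)))
    calls[i, , 1] <- a1
    calls[i, , 2] <- a2
  }
  if (is.null(pos)) pos <- seq_len(L)
  new_geno(
    calls,
    tibble::tibble(contig = contig, pos = pos,
                   ref = rep_len(ref, L), alt = rep_len(alt, L),
                   pass_site_filter = TRUE),
    sprintf("S%02d", seq_len(N))
  )
}

# allele-count tibble straight from counts
toy_ac <- function(n_ref, n_alt, contig = "3R", pos = NULL) {
  if (is.null(pos)) pos <- seq_along(n_ref)
  tibble::tibble(contig = contig, pos = pos,
                 n_ref = as.integer(n_ref), n_alt = as.integer(n_alt),
                 uninformative = (n_ref + n_alt) == 0L)
}

# haplotype matrix holding given haplotype sequences at given multiplicities
haps_with_freqs <- function(seqs, counts) {
  do.call(cbind, rep(seqs, times = counts))
}
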
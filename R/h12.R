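#' Garud haplotype-homozygosity statistics for one window
#'
#' Haplotype frequencies `f1 >= f2 >= ...` are obtained from exact sequence
#' identity over the window. `H1 = sum f_i^2`;
#' `H12 = (f1 + f2)^2 + sum_{i>=3} f_i^2` (pools the two most common
#' haplotypes, sensitising the statistic to soft sweeps);
#' `H123` pools the top three; `H2/H1 = (H1 - f1^2) / H1`.
#'
#' @param haps sites x haplotypes 0/1 matrix (no missing values).
#' @return Tibble with `h1`, `h12`, `h123`, `h2_h1`, `n_haplotypes`,
#'   `n_distinct`.
#' @export
h_statistics <- function(haps) {
  if (is.null(dim(haps)) || nrow(haps) < 1) abort("window must contain sites")
  if (ncol(haps) < 2) abort("need at least two haplotypes")
  key <- apply(haps, 2, paste, collapse = "")
  f <- sort(as.numeric(table(key)) / length(key), decreasing = TRUE)
  h1 <- sum(f^2)
  f2 <- if (length(f) >= 2) f[2] else 0
  f3 <- if (length(f) >= 3) f[3] else 0
  h12 <- (f[1] + f2)^2 + if (length(f) > 2) sum(f[-(1:2)]^2) else 0
  h123 <- (f[1] + f2 + f3)^2 + if (length(f) > 3) sum(f[-(1:3)]^2) else 0
  tibble(
    h1 = h1, h12 = h12, h123 = h123,
    h2_h1 = (h1 - f[1]^2) / h1,
    n_haplotypes = length(key),
    n_distinct = length(f)
  )
}

#' H12 scan in moving SNP windows
#'
#' Windows are defined in SNP counts (as in the underlying methodology);
#' physical spans are reported from the first and last SNP positions for
#' interpretation.
#'
#' @param haps sites x haplotypes 0/1 matrix.
#' @param positions per-site positions (default site index).
#' @param window_snps window width in SNPs (>= 2).
#' @param step_snps step in SNPs (default half the window).
#' @param contig contig label for the output.
#' @return An `h12_scan`: tibble with `contig`, `start_snp`, `end_snp`,
#'   `span_start`, `span_end`, `h1`, `h12`, `h123`, `h2_h1`.
#' @export
scan_h12 <- function(haps, positions = NULL, window_snps,
                     step_snps = NULL, contig = "3R") {
  if (window_snps < 2) abort("window must be at least 2 SNPs")
  if (is.null(step_snps)) step_snps <- max(1L, window_snps %/% 2L)
  if (is.null(positions)) positions <- seq_len(nrow(haps))
  L <- nrow(haps)
  if (L < window_snps) {
    return(structure(
      tibble(contig = character(), start_snp = integer(), end_snp = integer(),
             span_start = integer(), span_end = integer(),
             h1 = double(), h12 = double(), h123 = double(), h2_h1 = double()),
      class = c("h12_scan", "tbl_df", "tbl", "data.frame")
    ))
  }
  starts <- seq(1L, L - window_snps + 1L, by = step_snps)
  rows <- purrr::map_dfr(starts, function(s) {
    e <- s + window_snps - 1L
    st <- h_statistics(haps[s:e, , drop = FALSE])
    tibble(contig = contig, start_snp = s, end_snp = e,
           span_start = positions[s], span_end = positions[e],
           h1 = st$h1, h12 = st$h12, h123 = st$h123, h2_h1 = st$h2_h1)
  })
  class(rows) <- c("h12_scan", class(tibble()))
  rows
}

#' Calibrate the H12 window size against neutral haplotype diversity
#'
#' For each candidate window size the genome-wide H12 distribution is
#' computed and its 95th percentile recorded; the chosen size is the
#' *smallest* candidate whose 95th percentile is at or below `target`
#' (0.1 by default). When no candidate qualifies, the largest candidate is
#' returned with `calibrated = FALSE` and a warning.
#'
#' @param haps sites x haplotypes matrix.
#' @param candidate_sizes integer vector of window sizes in SNPs (>= 2
#'   candidates).
#' @param positions per-site positions.
#' @param target upper bound for the 95th percentile.
#' @return List with `window_snps` (chosen size), `calibrated` (logical),
#'   and `table` (tibble `window_snps`, `p95`, `n_windows`).
#' @export
calibrate_window_size <- function(haps, candidate_sizes, positions = NULL,
                                  target = 0.1) {
  if (length(candidate_sizes) < 1) abort("need candidate window sizes")
  candidate_sizes <- sort(unique(as.integer(candidate_sizes)))
  tab <- purrr::map_dfr(candidate_sizes, function(w) {
    sc <- scan_h12(haps, positions, window_snps = w)
    tibble(
      window_snps = w,
      p95 = if (nrow(sc)) as.numeric(quantile(sc$h12, 0.95)) else NA_real_,
      n_windows = nrow(sc)
    )
  })
  ok <- which(!is.na(tab$p95) & tab$p95 <= target)
  if (length(ok)) {
    list(window_snps = tab$window_snps[min(ok)], calibrated = TRUE, table = tab)
  } else {
    warn("no candidate window size met the calibration target; using largest")
    list(window_snps = max(candidate_sizes), calibrated = FALSE, table = tab)
  }
}

#' Flag H12 peaks above a threshold
#'
#' Maximal runs of consecutive scan windows with `h12 > threshold`; each
#' peak is reported with its span and its maximal window.
#'
#' @param scan an `h12_scan` tibble.
#' @param threshold H12 threshold in `(0, 1]` (default 0.1, the
#'   calibration constant).
#' @return Tibble with one row per peak: `contig`, `span_start`,
#'   `span_end`, `n_windows`, `max_h12`, `max_span_start`, `max_span_end`.
#' @export
find_peaks <- function(scan, threshold = 0.1) {
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  above <- scan$h12 > threshold
  if (!any(above)) {
    return(tibble(contig = character(), span_start = integer(),
                  span_end = integer(), n_windows = integer(),
                  max_h12 = double(), max_span_start = integer(),
                  max_span_end = integer()))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  purrr::map_dfr(runs, function(k) {
    i <- starts[k]:ends[k]
    j <- i[which.max(scan$h12[i])]
    tibble(
      contig = scan$contig[i[1]],
      span_start = min(scan$span_start[i]),
      span_end = max(scan$span_end[i]),
      n_windows = length(i),
      max_h12 = scan$h12[j],
      max_span_start = scan$span_start[j],
      max_span_end = scan$span_end[j]
    )
  })
}

#' Plot an H12 scan
#'
#' @param object an `h12_scan` tibble.
#' @param threshold optional horizontal reference line.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot h12_scan
#' @export
autoplot.h12_scan <- function(object, threshold = 0.1, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = (.data$span_start + .data$span_end) / 2, y = .data$h12)
  ) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "position (bp)", y = "H12") +
    ggplot2::theme_minimal()
}
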
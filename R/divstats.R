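#' Windowed nucleotide diversity, Watterson's theta and Tajima's D
#'
#' Per-site mean pairwise difference is computed from allele counts as
#' `n_ref * n_alt / choose(n, 2)` with `n = n_ref + n_alt`, summed within
#' each window and divided by the window's accessible-base count to give
#' per-base diversity. Watterson's theta per base is `S / a1 / n_accessible`
#' and Tajima's D uses the classical constants
#' (`a1 = sum 1/i`, `a2 = sum 1/i^2`, `b1`, `b2`, `c1`, `c2`, `e1`, `e2`)
#' evaluated at the per-window median called-allele count, since per-site
#' sample size varies with missingness. Windows with fewer than two
#' segregating sites, or median `n < 4`, carry `NA` for D.
#'
#' @param ac allele-count tibble from [allele_counts()].
#' @param windows window tibble from [accessible_windows()].
#' @return Tibble: windows plus `pi_per_base`, `theta_w_per_base`,
#'   `tajima_d`, `n_variants_used`.
#' @export
diversity_windows <- function(ac, windows) {
  n <- ac$n_ref + ac$n_alt
  seg <- ac$n_ref > 0 & ac$n_alt > 0
  pi_site <- ifelse(n >= 2, ac$n_ref * ac$n_alt / choose(n, 2), 0)
  wi <- window_index(windows, ac$contig, ac$pos)
  out <- windows %>% mutate(
    pi_sum = 0, S = 0L, med_n = NA_real_, n_variants_used = 0L
  )
  use <- !is.na(wi)
  if (any(use)) {
    agg <- tibble(wi = wi[use], pi = pi_site[use], seg = seg[use], n = n[use]) %>%
      group_by(.data$wi) %>%
      summarise(
        pi_sum = sum(.data$pi),
        S = sum(.data$seg),
        med_n = stats::median(.data$n[.data$seg]),
        n_variants_used = dplyr::n(),
        .groups = "drop"
      )
    out$pi_sum[agg$wi] <- agg$pi_sum
    out$S[agg$wi] <- agg$S
    out$med_n[agg$wi] <- agg$med_n
    out$n_variants_used[agg$wi] <- agg$n_variants_used
  }
  out %>%
    mutate(
      pi_per_base = ifelse(.data$n_accessible > 0,
                           .data$pi_sum / .data$n_accessible, NA_real_),
      theta_w_per_base = ifelse(
        .data$n_accessible > 0 & .data$S > 0 & .data$med_n >= 2,
        .data$S / tajima_a1(.data$med_n) / .data$n_accessible,
        ifelse(.data$n_accessible > 0, 0, NA_real_)
      ),
      tajima_d = tajima_d_value(.data$pi_sum, .data$S, .data$med_n)
    ) %>%
    select(-"pi_sum", -"med_n")
}

tajima_a1 <- function(n) {
  vapply(n, function(ni) {
    if (is.na(ni) || ni < 2) return(NA_real_)
    sum(1 / seq_len(floor(ni) - 1))
  }, numeric(1))
}

# Tajima's D from the pairwise-difference sum, segregating-site count and
# (median) sample size; NA where undefined (S < 2 or n < 4).
tajima_d_value <- function(pi_sum, S, n) {
  vapply(seq_along(S), function(i) {
    ni <- n[i]
    if (is.na(ni) || ni < 4 || is.na(S[i]) || S[i] < 2) return(NA_real_)
    ni <- floor(ni)
    a1 <- sum(1 / seq_len(ni - 1))
    a2 <- sum(1 / seq_len(ni - 1)^2)
    b1 <- (ni + 1) / (3 * (ni - 1))
    b2 <- 2 * (ni^2 + ni + 3) / (9 * ni * (ni - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (ni + 2) / (a1 * ni) + a2 / a1^2
    e1 <- c1 / a1
    e2 <- c2 / (a1^2 + a2)
    v <- e1 * S[i] + e2 * S[i] * (S[i] - 1)
    if (v <= 0) return(NA_real_)
    (pi_sum[i] - S[i] / a1) / sqrt(v)
  }, numeric(1))
}

# Bhatia/Hudson per-site FST components; sites with n1 < 2 or n2 < 2 get NA
hudson_site_components <- function(ac1, ac2) {
  n1 <- ac1$n_ref + ac1$n_alt
  n2 <- ac2$n_ref + ac2$n_alt
  p1 <- ac1$n_alt / n1
  p2 <- ac2$n_alt / n2
  ok <- n1 >= 2 & n2 >= 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  num[!ok] <- NA_real_
  den[!ok] <- NA_real_
  list(num = num, den = den, ok = ok)
}

#' Hudson's FST (Bhatia estimator)
#'
#' Per-site numerator `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`
#' and denominator `p1(1-p2) + p2(1-p1)`; window and genome-wide values are
#' the *ratio of sums* of these components, never the mean of per-site
#' ratios. Sites where either cohort has fewer than two called alleles are
#' skipped. Values are reported unclipped: window estimates below zero are
#' estimator noise and are retained.
#'
#' @param ac1,ac2 allele-count tibbles for the two cohorts, aligned on the
#'   same variants.
#' @param windows optional window tibble; when `NULL` only the genome-wide
#'   value is returned.
#' @return A list of class `fst_result`: `genome_wide` (scalar), `windows`
#'   (tibble with `fst`, `n_variants_used`, or `NULL`), `per_site` (tibble
#'   with `num`, `den`).
#' @export
hudson_fst <- function(ac1, ac2, windows = NULL) {
  stopifnot(nrow(ac1) == nrow(ac2))
  comp <- hudson_site_components(ac1, ac2)
  gw <- sum(comp$num, na.rm = TRUE) / sum(comp$den, na.rm = TRUE)
  win <- NULL
  if (!is.null(windows)) {
    wi <- window_index(windows, ac1$contig, ac1$pos)
    use <- !is.na(wi) & comp$ok
    agg <- tibble(wi = wi[use], num = comp$num[use], den = comp$den[use]) %>%
      group_by(.data$wi) %>%
      summarise(num = sum(.data$num), den = sum(.data$den),
                n_variants_used = dplyr::n(), .groups = "drop")
    win <- windows %>%
      mutate(fst = NA_real_, n_variants_used = 0L)
    win$fst[agg$wi] <- agg$num / agg$den
    win$n_variants_used[agg$wi] <- agg$n_variants_used
  }
  structure(
    list(
      genome_wide = gw,
      windows = win,
      per_site = tibble(contig = ac1$contig, pos = ac1$pos,
                        num = comp$num, den = comp$den)
    ),
    class = "fst_result"
  )
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("<fst_result> genome-wide FST = %.4f (%d sites)\n",
              x$genome_wide, sum(!is.na(x$per_site$num))))
  invisible(x)
}

#' @method tidy fst_result
#' @export
tidy.fst_result <- function(x, ...) {
  if (is.null(x$windows)) x$per_site else x$windows
}

#' @method glance fst_result
#' @export
glance.fst_result <- function(x, ...) {
  tibble(fst = x$genome_wide, n_sites = sum(!is.na(x$per_site$num)))
}

#' Absolute divergence Dxy per accessible base
#'
#' Per-site `p1 (1 - p2) + p2 (1 - p1)` summed within windows and divided
#' by the accessible-base count. Symmetric in the two cohorts.
#'
#' @inheritParams hudson_fst
#' @return Windows tibble with `dxy_per_base` and `n_variants_used` (plus a
#'   `genome_wide` attribute giving the all-window per-base mean).
#' @export
dxy_windows <- function(ac1, ac2, windows) {
  stopifnot(nrow(ac1) == nrow(ac2))
  n1 <- ac1$n_ref + ac1$n_alt
  n2 <- ac2$n_ref + ac2$n_alt
  p1 <- ac1$n_alt / n1
  p2 <- ac2$n_alt / n2
  ok <- n1 >= 2 & n2 >= 2
  d <- p1 * (1 - p2) + p2 * (1 - p1)
  wi <- window_index(windows, ac1$contig, ac1$pos)
  use <- !is.na(wi) & ok
  agg <- tibble(wi = wi[use], d = d[use]) %>%
    group_by(.data$wi) %>%
    summarise(dsum = sum(.data$d), n_variants_used = dplyr::n(),
              .groups = "drop")
  out <- windows %>% mutate(dxy_per_base = 0, n_variants_used = 0L)
  out$dxy_per_base[agg$wi] <- agg$dsum / out$n_accessible[agg$wi]
  out$n_variants_used[agg$wi] <- agg$n_variants_used
  out$dxy_per_base[out$n_accessible == 0] <- NA_real_
  attr(out, "genome_wide") <- sum(d[use]) / sum(windows$n_accessible)
  out
}

#' Folded site frequency spectrum
#'
#' Histogram of minor-allele counts `1 .. floor(n/2)` over segregating
#' sites with a full complement of called alleles. Sites with any missing
#' call are dropped by default so the spectrum has a single sample size;
#' monomorphic sites are excluded.
#'
#' @param ac allele-count tibble.
#' @param n_alleles expected called-allele count per site (default: the
#'   maximum observed).
#' @return Tibble `minor_count`, `n_sites`; total sites used stored in the
#'   `n_used` attribute.
#' @export
folded_sfs <- function(ac, n_alleles = NULL) {
  tot <- ac$n_ref + ac$n_alt
  if (is.null(n_alleles)) n_alleles <- max(tot)
  use <- tot == n_alleles & ac$n_ref > 0 & ac$n_alt > 0
  minor <- pmin(ac$n_alt[use], ac$n_ref[use])
  bins <- seq_len(floor(n_alleles / 2))
  out <- tibble(
    minor_count = bins,
    n_sites = as.integer(tabulate(minor, nbins = max(bins)))
  )
  attr(out, "n_used") <- sum(use)
  out
}

#' Rank the most differentiated windows and attach overlapping genes
#'
#' Orders windows by a statistic column (descending) and reports the top
#' `k` together with the IDs of genes whose spans intersect the window.
#' Overlap is inclusive on both ends: a gene ending exactly at a window's
#' start base is listed.
#'
#' @param windows result tibble carrying the statistic (e.g. from
#'   [hudson_fst()] `$windows`).
#' @param genes gene tibble from [read_gff_genes()].
#' @param statistic name of the column to rank on (default `"fst"`).
#' @param k number of windows to report.
#' @return Tibble of the top windows with a `genes` list-column and
#'   `gene_ids` comma-collapsed string column.
#' @export
rank_top_windows <- function(windows, genes, statistic = "fst", k = 5L) {
  stopifnot(statistic %in% names(windows))
  top <- windows %>%
    filter(!is.na(.data[[statistic]])) %>%
    arrange(desc(.data[[statistic]])) %>%
    head(k)
  top$genes <- purrr::pmap(
    list(top$contig, top$start, top$end),
    function(ctg, s, e) {
      hit <- genes$contig == ctg & genes$start <= e & genes$end >= s
      genes$gene_id[hit]
    }
  )
  top$gene_ids <- purrr::map_chr(top$genes, paste, collapse = ",")
  top
}

#' Plot a windowed statistic along the genome
#'
#' @param windows result tibble with `contig`, `start` and the statistic.
#' @param statistic column name to plot.
#' @return A ggplot object.
#' @export
plot_windows <- function(windows, statistic) {
  ggplot2::ggplot(
    windows,
    ggplot2::aes(x = (.data$start + .data$end) / 2, y = .data[[statistic]])
  ) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$contig), scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = statistic) +
    ggplot2::theme_minimal()
}
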
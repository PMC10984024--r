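#' Principal component analysis with the Patterson scaler
#'
#' Each variant row of the dosage matrix is centred by twice its mean
#' allele frequency and divided by `sqrt(p * (1 - p))`, the standard
#' deviation expected under binomial sampling at the mean frequency `p`.
#' Missing dosages are mean-imputed before scaling. The decomposition is
#' by singular values of the scaled matrix; variants with zero variance
#' (or undefined scale) are dropped. Components are sign-oriented so the
#' sample coordinate with the largest magnitude on each axis is positive,
#' making results reproducible across platforms.
#'
#' @param dosages variants x samples matrix of 0/1/2 dosages (`NA` allowed).
#' @param n_components number of components to retain (default 10).
#' @return An object of class `pca_fit`: list with `coordinates` (tibble,
#'   one row per sample: `sample_id`, `PC1`..), `explained` (variance
#'   fractions), `n_variants_used`.
#' @export
pca_patterson <- function(dosages, n_components = 10L) {
  N <- ncol(dosages)
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- sprintf("sample%03d", seq_len(N))
  }
  if (n_components > N) {
    warn("fewer samples than components requested; reducing")
    n_components <- N
  }
  mu <- rowMeans(dosages, na.rm = TRUE)
  p <- mu / 2
  scale <- sqrt(p * (1 - p))
  ok <- is.finite(scale) & scale > 0
  x <- dosages[ok, , drop = FALSE]
  mu <- mu[ok]
  # mean-imputation of missing dosages, then centre and scale
  naidx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(naidx)) x[naidx] <- mu[naidx[, 1]]
  x <- (x - mu) / scale[ok]
  if (nrow(x) < n_components) {
    warn("fewer informative variants than components; reducing")
    n_components <- nrow(x)
  }
  sv <- svd(x, nu = 0, nv = n_components)
  coords <- sv$v * rep(sv$d[seq_len(n_components)], each = N)
  # deterministic orientation: largest-|coordinate| entry positive
  for (k in seq_len(n_components)) {
    i <- which.max(abs(coords[, k]))
    if (coords[i, k] < 0) coords[, k] <- -coords[, k]
  }
  colnames(coords) <- paste0("PC", seq_len(n_components))
  structure(
    list(
      coordinates = bind_cols(tibble(sample_id = colnames(dosages)),
                              as_tibble(coords)),
      explained = sv$d^2 / sum(sv$d^2),
      n_variants_used = nrow(x)
    ),
    class = "pca_fit"
  )
}

#' @export
print.pca_fit <- function(x, ...) {
  cat(sprintf("<pca_fit> %d samples, %d variants, PC1 %.1f%% / PC2 %.1f%%\n",
              nrow(x$coordinates), x$n_variants_used,
              100 * x$explained[1], 100 * x$explained[2]))
  invisible(x)
}

#' @method tidy pca_fit
#' @export
tidy.pca_fit <- function(x, ...) x$coordinates

#' @method glance pca_fit
#' @export
glance.pca_fit <- function(x, ...) {
  tibble(
    n_samples = nrow(x$coordinates),
    n_variants_used = x$n_variants_used,
    pve_pc1 = x$explained[1],
    pve_pc2 = x$explained[2]
  )
}

#' Plot the first two principal components
#'
#' @param object a `pca_fit`.
#' @param meta optional sample metadata tibble with `sample_id` and
#'   `cohort` for colouring.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot pca_fit
#' @export
autoplot.pca_fit <- function(object, meta = NULL, ...) {
  d <- object$coordinates
  if (!is.null(meta)) d <- left_join(d, meta, by = "sample_id")
  aes <- if (!is.null(meta)) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$cohort)
  } else {
    ggplot2::aes(x = .data$PC1, y = .data$PC2)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2])
    ) +
    ggplot2::theme_minimal()
}

#' Ancestry-informative-marker fractions and taxon assignment
#'
#' For every sample, the AIM fraction is the share of taxon-A diagnostic
#' alleles among all called alleles at panel sites:
#' `(# A alleles) / (2 * # called panel sites)`. Cohort values are the mean
#' over members with at least one called site. Assignment follows the
#' published convention: a cohort is "intermediate" when its mean fraction
#' is strictly between 0.05 and 0.95; at or beyond those bounds it is
#' assigned to the nearer taxon.
#'
#' @param g a `geno` object covering the panel sites.
#' @param panel tibble with `contig`, `pos`, `a_allele`, `b_allele`
#'   (nucleotides diagnostic for taxon A and taxon B).
#' @param meta optional metadata tibble (`sample_id`, `cohort`) for cohort
#'   summaries.
#' @return A list of class `aim_report`: `samples` (tibble `sample_id`,
#'   `aim_fraction`, `n_called_sites`) and `cohorts` (tibble `cohort`,
#'   `mean_fraction`, `assignment`), the latter `NULL` without `meta`.
#' @export
aim_fraction <- function(g, panel, meta = NULL) {
  panel <- as_tibble(panel)
  if (!nrow(panel)) abort("AIM panel is empty")
  key_g <- paste(g$variants$contig, g$variants$pos)
  key_p <- paste(panel$contig, panel$pos)
  hit <- match(key_p, key_g)
  if (anyNA(hit)) abort("panel contains positions absent from the genotype data")
  vt <- g$variants[hit, ]
  a_is_alt <- panel$a_allele == vt$alt
  a_is_ref <- panel$a_allele == vt$ref
  if (any(!a_is_alt & !a_is_ref)) {
    abort("panel A-allele matches neither ref nor alt at some sites")
  }
  sub <- g$calls[hit, , , drop = FALSE]
  # recode calls to 1 = A allele, 0 = B allele
  a_code <- array(rep(ifelse(a_is_alt, 1L, 0L), length(g$samples) * 2L),
                  dim = dim(sub))
  is_a <- (sub == a_code)
  n_a <- rowSums(aperm(is_a, c(2, 1, 3)), dims = 1, na.rm = TRUE)
  n_called <- rowSums(aperm(!is.na(sub), c(2, 1, 3)), dims = 1) / 2
  frac <- ifelse(n_called > 0, n_a / (2 * n_called), NA_real_)
  samples <- tibble(
    sample_id = g$samples,
    aim_fraction = frac,
    n_called_sites = as.integer(n_called)
  )
  cohorts <- NULL
  if (!is.null(meta)) {
    if (any(is.na(frac))) {
      warn("samples with no called panel site excluded from cohort means")
    }
    cohorts <- samples %>%
      inner_join(meta, by = "sample_id") %>%
      filter(!is.na(.data$aim_fraction)) %>%
      group_by(.data$cohort) %>%
      summarise(mean_fraction = mean(.data$aim_fraction), .groups = "drop") %>%
      mutate(assignment = dplyr::case_when(
        .data$mean_fraction >= 0.95 ~ "taxon-A",
        .data$mean_fraction <= 0.05 ~ "taxon-B",
        TRUE ~ "intermediate"
      ))
  }
  structure(list(samples = samples, cohorts = cohorts), class = "aim_report")
}

#' @export
print.aim_report <- function(x, ...) {
  cat(sprintf("<aim_report> %d samples\n", nrow(x$samples)))
  if (!is.null(x$cohorts)) print(x$cohorts)
  invisible(x)
}

#' @method tidy aim_report
#' @export
tidy.aim_report <- function(x, ...) x$samples

#' @method glance aim_report
#' @export
glance.aim_report <- function(x, ...) {
  if (is.null(x$cohorts)) {
    tibble(n_samples = nrow(x$samples))
  } else {
    tibble(
      n_samples = nrow(x$samples),
      n_cohorts = nrow(x$cohorts),
      n_intermediate = sum(x$cohorts$assignment == "intermediate")
    )
  }
}
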
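#' Allele-frequency differences between two cohorts (DAF)
#'
#' For each biallelic site, computes the called-allele frequency in each
#' cohort, the absolute frequency difference, and the genotyping success
#' (fraction of samples across both cohorts with a called genotype).
#' Sites with success below `min_success` are excluded, as are sites where
#' either cohort has no called allele. Marker tiers follow the published
#' thresholds: `fixed` at `|dAF| = 1`, `ge98` above 0.98, `ge85` above
#' 0.85 (strict inequalities, fixation an exact tier), `none` otherwise.
#'
#' @param g a `geno` object.
#' @param meta sample metadata tibble (`sample_id`, `cohort`).
#' @param cohort_a,cohort_b cohort labels; A is the focal taxon markers
#'   are oriented toward.
#' @param min_success genotyping-success threshold (default 0.10).
#' @return Tibble with `contig`, `pos`, `ref`, `alt`, `freq_a`, `freq_b`,
#'   `daf`, `success`, `tier`.
#' @export
compute_daf <- function(g, meta, cohort_a, cohort_b, min_success = 0.10) {
  ids_a <- meta$sample_id[meta$cohort == cohort_a]
  ids_b <- meta$sample_id[meta$cohort == cohort_b]
  if (!length(ids_a) || !length(ids_b)) abort("empty cohort")
  aca <- allele_counts(g, ids_a)
  acb <- allele_counts(g, ids_b)
  n_total <- length(ids_a) + length(ids_b)
  called <- (aca$n_ref + aca$n_alt + acb$n_ref + acb$n_alt) / 2
  success <- called / n_total
  pa <- allele_freq(aca)
  pb <- allele_freq(acb)
  daf <- abs(pa - pb)
  keep <- success >= min_success & !aca$uninformative & !acb$uninformative &
    is.finite(daf)
  tibble(
    contig = g$variants$contig,
    pos = g$variants$pos,
    ref = g$variants$ref,
    alt = g$variants$alt,
    freq_a = pa,
    freq_b = pb,
    daf = daf,
    success = success
  )[keep, ] %>%
    mutate(tier = dplyr::case_when(
      .data$daf >= 1 - 1e-12 ~ "fixed",
      .data$daf > 0.98 ~ "ge98",
      .data$daf > 0.85 ~ "ge85",
      TRUE ~ "none"
    ))
}

#' Build a diagnostic marker panel from a DAF table
#'
#' Selects every site at or above the requested tier (tiers nest:
#' `fixed` is a subset of `ge98` is a subset of `ge85`) and orients each
#' marker toward the focal cohort: the marker allele is the one at higher
#' frequency in cohort A than in cohort B.
#'
#' @param daf tibble from [compute_daf()].
#' @param tier `"fixed"`, `"ge98"` or `"ge85"`.
#' @return Tibble with `contig`, `pos`, `a_allele`, `b_allele`, `tier`,
#'   plus a per-contig composition summary in the `composition` attribute.
#'   Empty panels are returned (with a warning), not an error.
#' @export
build_panel <- function(daf, tier = c("ge85", "ge98", "fixed")) {
  tier <- match.arg(tier)
  want <- switch(tier,
    fixed = "fixed",
    ge98 = c("fixed", "ge98"),
    ge85 = c("fixed", "ge98", "ge85")
  )
  sel <- daf %>% filter(.data$tier %in% want)
  a_is_alt <- sel$freq_a > sel$freq_b
  panel <- sel %>%
    mutate(
      a_allele = ifelse(a_is_alt, .data$alt, .data$ref),
      b_allele = ifelse(a_is_alt, .data$ref, .data$alt)
    ) %>%
    select("contig", "pos", "a_allele", "b_allele", "tier")
  if (!nrow(panel)) warn("marker panel is empty at the requested tier")
  attr(panel, "composition") <- panel %>% count(.data$contig, name = "n_markers")
  panel
}

#' Individual allelic percentage over a marker panel
#'
#' Per sample: `100 * (# panel A-oriented alleles carried at called
#' markers) / (2 * # called markers)`. Missing genotypes shrink the
#' denominator rather than counting as B alleles; a sample with zero
#' called markers gets `NA`.
#'
#' @param g a `geno` object covering the panel sites.
#' @param panel tibble from [build_panel()].
#' @return Tibble `sample_id`, `allelic_percentage`, `n_called_markers`,
#'   `n_missing_markers`.
#' @export
allelic_percentage <- function(g, panel) {
  if (!nrow(panel)) abort("panel is empty")
  rep_ <- aim_fraction(g, panel)
  rep_$samples %>%
    mutate(
      allelic_percentage = 100 * .data$aim_fraction,
      n_called_markers = .data$n_called_sites,
      n_missing_markers = nrow(panel) - .data$n_called_sites
    ) %>%
    select("sample_id", "allelic_percentage", "n_called_markers",
           "n_missing_markers")
}

#' Classify individuals by allelic percentage
#'
#' Strict cut-offs as suggested by the discrimination analysis: above
#' `hi_cutoff` percent of focal-taxon alleles assigns taxon A, below
#' `lo_cutoff` assigns taxon B, anything else (including samples with no
#' called marker) is left unassigned.
#'
#' @param ap tibble from [allelic_percentage()].
#' @param hi_cutoff,lo_cutoff percentages (defaults 80 and 20).
#' @param truth optional tibble (`sample_id`, `cohort`) with true labels;
#'   when given, per-label accuracy is reported for labels matching
#'   `taxon_a_label` / `taxon_b_label`.
#' @param taxon_a_label,taxon_b_label truth labels corresponding to the
#'   two taxa.
#' @return A list of class `classification_report`: `samples` tibble with
#'   `label`, and `accuracy` tibble (`NULL` without truth).
#' @export
classify_samples <- function(ap, hi_cutoff = 80, lo_cutoff = 20, truth = NULL,
                             taxon_a_label = "taxon-A",
                             taxon_b_label = "taxon-B") {
  if (hi_cutoff <= lo_cutoff) abort("hi_cutoff must exceed lo_cutoff")
  samples <- ap %>%
    mutate(label = dplyr::case_when(
      is.na(.data$allelic_percentage) ~ "unassigned",
      .data$allelic_percentage > hi_cutoff ~ "taxon-A",
      .data$allelic_percentage < lo_cutoff ~ "taxon-B",
      TRUE ~ "unassigned"
    ))
  accuracy <- NULL
  if (!is.null(truth)) {
    joined <- samples %>%
      inner_join(truth, by = "sample_id") %>%
      filter(.data$cohort %in% c(taxon_a_label, taxon_b_label)) %>%
      mutate(expected = ifelse(.data$cohort == taxon_a_label,
                               "taxon-A", "taxon-B"))
    accuracy <- joined %>%
      group_by(.data$cohort) %>%
      summarise(
        n = dplyr::n(),
        n_correct = sum(.data$label == .data$expected),
        accuracy = mean(.data$label == .data$expected),
        .groups = "drop"
      )
    attr(accuracy, "overall") <- mean(joined$label == joined$expected)
  }
  structure(list(samples = samples, accuracy = accuracy),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %d samples: %s\n",
              nrow(x$samples),
              paste(names(table(x$samples$label)),
                    table(x$samples$label), sep = "=", collapse = ", ")))
  if (!is.null(x$accuracy)) {
    cat(sprintf("overall accuracy on labelled taxa: %.4f\n",
                attr(x$accuracy, "overall")))
  }
  invisible(x)
}

#' @method tidy classification_report
#' @export
tidy.classification_report <- function(x, ...) x$samples

#' @method glance classification_report
#' @export
glance.classification_report <- function(x, ...) {
  tibble(
    n_samples = nrow(x$samples),
    n_unassigned = sum(x$samples$label == "unassigned"),
    overall_accuracy = if (is.null(x$accuracy)) NA_real_
                       else attr(x$accuracy, "overall")
  )
}

#' Marker-matrix export for classification plots
#'
#' Builds the samples x markers genotype-class matrix used for tile plots:
#' each cell is `"A"` (homozygous focal allele), `"B"`, `"het"` or
#' `"missing"`, with the allelic percentage attached per sample.
#'
#' @param g a `geno` object covering the panel sites.
#' @param panel tibble from [build_panel()].
#' @return Long tibble `sample_id`, `contig`, `pos`, `genotype_class`,
#'   `allelic_percentage`.
#' @export
marker_matrix <- function(g, panel) {
  key_g <- paste(g$variants$contig, g$variants$pos)
  hit <- match(paste(panel$contig, panel$pos), key_g)
  vt <- g$variants[hit, ]
  a_is_alt <- panel$a_allele == vt$alt
  sub <- g$calls[hit, , , drop = FALSE]
  a_count <- (sub[, , 1] == ifelse(a_is_alt, 1L, 0L)) +
    (sub[, , 2] == ifelse(a_is_alt, 1L, 0L))
  cls <- matrix("missing", nrow = nrow(panel), ncol = length(g$samples))
  cls[!is.na(a_count) & a_count == 2] <- "A"
  cls[!is.na(a_count) & a_count == 1] <- "het"
  cls[!is.na(a_count) & a_count == 0] <- "B"
  ap <- allelic_percentage(g, panel)
  tibble(
    sample_id = rep(g$samples, each = nrow(panel)),
    contig = rep(panel$contig, times = length(g$samples)),
    pos = rep(panel$pos, times = length(g$samples)),
    genotype_class = as.vector(cls)
  ) %>%
    left_join(ap %>% select("sample_id", "allelic_percentage"),
              by = "sample_id")
}
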
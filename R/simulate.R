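#' Simulate per-taxon allele frequencies under Balding-Nichols divergence
#'
#' Each taxon's frequency at each variant is drawn from a Beta distribution
#' centred on a shared ancestral frequency `p` with spread controlled by a
#' drift parameter `F`: `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`. Under
#' this model the expected Hudson FST between two taxa with drift `F` is
#' close to `F`, which is how synthetic divergence is matched to the
#' interspecific scale observed in the mosquito data (pairwise FST ~ 0.03).
#' `F = 0` returns the ancestral frequency unchanged.
#'
#' The ancestral frequency is drawn from Uniform(`anc_min`, `anc_max`); the
#' default support excludes rare ancestral alleles to avoid a flood of
#' monomorphic simulated sites.
#'
#' @param n_variants number of variants.
#' @param taxa tibble (or data frame) with columns `name` and `drift`
#'   (`F` in `[0, 1)`); see [taxon_model()].
#' @param seed integer seed.
#' @param anc_min,anc_max support of the ancestral frequency draw.
#' @return A list with `ancestral` (numeric vector) and `freqs`, a named
#'   list of per-taxon frequency vectors.
#' @export
simulate_frequencies <- function(n_variants, taxa, seed,
                                 anc_min = 0.05, anc_max = 0.95) {
  if (n_variants < 1) abort("`n_variants` must be >= 1")
  taxa <- as_tibble(taxa)
  if (any(taxa$drift >= 1 | taxa$drift < 0)) abort("drift F must be in [0, 1)")
  withr_seed(seed)
  p <- runif(n_variants, anc_min, anc_max)
  freqs <- lapply(seq_len(nrow(taxa)), function(i) {
    drift_frequencies(p, taxa$drift[i])
  })
  names(freqs) <- taxa$name
  list(ancestral = p, freqs = freqs)
}

#' One branch of Balding-Nichols drift
#'
#' Draws descendant frequencies from `Beta` centred on `p` with drift `f`.
#' Composable into arbitrary tree topologies by repeated application.
#' Uses the current RNG state (seed management is the caller's job).
#'
#' @param p ancestral frequency vector.
#' @param f drift parameter in `[0, 1)`.
#' @return Frequency vector of the same length.
#' @export
drift_frequencies <- function(p, f) {
  if (f < 0 || f >= 1) abort("drift F must be in [0, 1)")
  if (f == 0) return(p)
  k <- (1 - f) / f
  rbeta(length(p), p * k, (1 - p) * k)
}

#' Taxon model constructor
#'
#' @param name taxon label.
#' @param drift Balding-Nichols drift `F` in `[0, 1)`.
#' @param cohort_size number of diploid individuals sampled from the taxon.
#' @return One-row tibble.
#' @export
taxon_model <- function(name, drift, cohort_size) {
  if (cohort_size < 1) abort("cohort_size must be >= 1")
  tibble(name = name, drift = drift, cohort_size = as.integer(cohort_size))
}

#' Mix two source frequency vectors
#'
#' `p_admixed = alpha * p_a + (1 - alpha) * p_b`, per variant, emulating a
#' population formed by admixture of two sources.
#'
#' @param freq_a,freq_b source frequency vectors of equal length.
#' @param alpha mixing proportion of `freq_a` in `[0, 1]`.
#' @return Frequency vector.
#' @export
simulate_admixed <- function(freq_a, freq_b, alpha) {
  if (alpha < 0 || alpha > 1) abort("`alpha` must be in [0, 1]")
  if (length(freq_a) != length(freq_b)) abort("source frequency vectors differ in length")
  alpha * freq_a + (1 - alpha) * freq_b
}

#' Simulate diploid genotypes from allele frequencies
#'
#' Each allele is an independent Bernoulli(`p`) draw (Hardy-Weinberg within
#' the cohort); optional genotype-level missingness is applied afterwards.
#'
#' @param freqs alt-allele frequency vector.
#' @param cohort_size number of diploid samples.
#' @param seed integer seed.
#' @param missing_rate probability a genotype is set to missing.
#' @param sample_prefix prefix for generated sample ids.
#' @param contig,pos_start variant coordinates for the variant table.
#' @return A `geno` object with ref "A", alt "T" placeholder alleles.
#' @export
simulate_genotypes <- function(freqs, cohort_size, seed, missing_rate = 0,
                               sample_prefix = "S", contig = "3R",
                               pos_start = 1L) {
  if (any(freqs < 0 | freqs > 1)) abort("frequencies must be in [0, 1]")
  withr_seed(seed)
  L <- length(freqs)
  N <- as.integer(cohort_size)
  calls <- array(NA_integer_, dim = c(L, N, 2))
  calls[, , 1] <- rbinom(L * N, 1L, rep(freqs, times = N))
  calls[, , 2] <- rbinom(L * N, 1L, rep(freqs, times = N))
  if (missing_rate > 0) {
    drop <- matrix(runif(L * N) < missing_rate, nrow = L)
    idx <- which(drop, arr.ind = TRUE)
    calls[cbind(idx, 1L)] <- NA_integer_
    calls[cbind(idx, 2L)] <- NA_integer_
  }
  variants <- tibble(
    contig = contig,
    pos = seq.int(pos_start, length.out = L),
    ref = "A", alt = "T", pass_site_filter = TRUE
  )
  new_geno(calls, variants, sprintf("%s%04d", sample_prefix, seq_len(N)))
}

#' Simulate cohort allele counts directly
#'
#' Draws the alternate-allele count of a cohort of `cohort_size` diploids
#' at each site as Binomial(`2 * cohort_size`, `p`) -- the exact sampling
#' distribution of [allele_counts()] applied to [simulate_genotypes()]
#' output without missingness, but much cheaper for replicate-heavy
#' calibration runs.
#'
#' @param freqs alt-allele frequency vector.
#' @param cohort_size diploid cohort size.
#' @param seed integer seed.
#' @param contig,pos_start variant coordinates.
#' @return Allele-count tibble as from [allele_counts()].
#' @export
simulate_allele_counts <- function(freqs, cohort_size, seed, contig = "3R",
                                   pos_start = 1L) {
  withr_seed(seed)
  n <- 2L * as.integer(cohort_size)
  alt <- rbinom(length(freqs), n, freqs)
  tibble(
    contig = contig,
    pos = seq.int(pos_start, length.out = length(freqs)),
    n_ref = n - alt,
    n_alt = alt,
    uninformative = FALSE
  )
}

#' Sweep configuration for haplotype simulation
#'
#' @param contig contig name.
#' @param center sweep centre position (1-based).
#' @param frequency total frequency of sweeping haplotypes in `(0, 1]`.
#' @param flank half-width of the swept region in bases.
#' @param n_founders number of distinct founder haplotypes sharing the
#'   sweep frequency equally (1 = hard sweep, >1 = soft sweep).
#' @return One-row tibble.
#' @export
sweep_config <- function(contig = "3R", center, frequency, flank,
                         n_founders = 1L) {
  if (frequency <= 0 || frequency > 1) abort("sweep frequency must be in (0, 1]")
  tibble(contig = contig, center = as.integer(center), frequency = frequency,
         flank = as.integer(flank), n_founders = as.integer(n_founders))
}

#' Simulate phased haplotypes with an optional selective sweep
#'
#' The neutral background draws every site independently at a per-site
#' frequency (linkage is deliberately absent: the generator exists to
#' calibrate and sanity-check haplotype-homozygosity statistics, not to
#' emulate recombination). Under a sweep, a fraction `frequency` of
#' haplotypes is replaced by `n_founders` founder sequences (equal shares)
#' across all sites within `flank` of `center`.
#'
#' @param n_variants number of variant sites.
#' @param n_haplotypes number of haplotypes (even).
#' @param seed integer seed.
#' @param freqs optional per-site frequencies (default Uniform(0.05, 0.95)).
#' @param sweep optional [sweep_config()] row.
#' @param pos_step physical distance between adjacent sites.
#' @return A list with `haps` (matrix sites x haplotypes), `positions`,
#'   and `contig`.
#' @export
simulate_haplotypes <- function(n_variants, n_haplotypes, seed, freqs = NULL,
                                sweep = NULL, pos_step = 100L) {
  if (n_haplotypes %% 2 != 0) abort("`n_haplotypes` must be even")
  withr_seed(seed)
  if (is.null(freqs)) freqs <- runif(n_variants, 0.05, 0.95)
  haps <- matrix(
    rbinom(n_variants * n_haplotypes, 1L, rep(freqs, times = n_haplotypes)),
    nrow = n_variants
  )
  positions <- seq.int(1L, by = as.integer(pos_step), length.out = n_variants)
  contig <- "3R"
  if (!is.null(sweep)) {
    sweep <- as_tibble(sweep)
    contig <- sweep$contig[1]
    lo <- sweep$center[1] - sweep$flank[1]
    hi <- sweep$center[1] + sweep$flank[1]
    if (lo < min(positions) || hi > max(positions)) {
      warn("sweep flank clipped to simulated region")
    }
    in_flank <- positions >= lo & positions <= hi
    n_carriers <- round(sweep$frequency[1] * n_haplotypes)
    carriers <- sample(n_haplotypes, n_carriers)
    founder_of <- rep(seq_len(sweep$n_founders[1]), length.out = n_carriers)
    founders <- matrix(
      rbinom(sum(in_flank) * sweep$n_founders[1], 1L,
             rep(freqs[in_flank], times = sweep$n_founders[1])),
      ncol = sweep$n_founders[1]
    )
    for (k in seq_len(sweep$n_founders[1])) {
      cols <- carriers[founder_of == k]
      haps[in_flank, cols] <- founders[, k]
    }
  }
  list(haps = haps, positions = positions, contig = contig)
}

#' Simulate a four-taxon tree with optional introgression
#'
#' Emulates the gene-flow test design: two sister populations P1 and P2 of
#' one taxon (low mutual divergence), a source taxon P3 at interspecific
#' divergence, and a deep outgroup. Optionally a fraction `replacement` of
#' P2's ancestry is replaced by P3 (`p2' = (1 - r) p2 + r p3`), the
#' frequency-level analogue of recent unidirectional gene flow P3 -> P2.
#' Default branch drifts place P1-P2 divergence near FST 0.02 and
#' P1-P3 near the interspecific scale.
#'
#' @param n_variants sites to simulate.
#' @param seed integer seed.
#' @param replacement fraction of P2 ancestry replaced by P3 (0 = clean
#'   tree).
#' @param drift_internal drift of the (P1,P2) ancestor branch.
#' @param drift_child drift of each of the P1 and P2 terminal branches.
#' @param drift_source drift of the P3 branch.
#' @param drift_outgroup drift of the outgroup branch.
#' @return Named list of population frequency vectors `p1`, `p2`, `p3`,
#'   `outgroup`, plus `ancestral`.
#' @export
simulate_introgression <- function(n_variants, seed, replacement = 0.1,
                                   drift_internal = 0.01, drift_child = 0.01,
                                   drift_source = 0.05,
                                   drift_outgroup = 0.3) {
  withr_seed(seed)
  p <- runif(n_variants, 0.05, 0.95)
  out <- drift_frequencies(p, drift_outgroup)
  p3 <- drift_frequencies(p, drift_source)
  p12 <- drift_frequencies(p, drift_internal)
  p1 <- drift_frequencies(p12, drift_child)
  p2 <- drift_frequencies(p12, drift_child)
  if (replacement > 0) p2 <- (1 - replacement) * p2 + replacement * p3
  list(p1 = p1, p2 = p2, p3 = p3, outgroup = out, ancestral = p)
}

#' Copy-number truth record
#'
#' @param sample_id sample carrying the event.
#' @param contig contig name.
#' @param start_window,end_window window indices (inclusive) of the event.
#' @param copy_number true copy number (integer, != 2).
#' @return One-row tibble.
#' @export
cnv_truth <- function(sample_id, contig, start_window, end_window, copy_number) {
  if (end_window < start_window) abort("end_window must be >= start_window")
  if (copy_number < 0) abort("copy number must be >= 0")
  tibble(sample_id = sample_id, contig = contig,
         start_window = as.integer(start_window),
         end_window = as.integer(end_window),
         copy_number = as.integer(copy_number))
}

# unimodal quadratic GC bias, peaking at gc = 0.45; multiplicative factor
default_gc_bias <- function(gc) {
  pmax(0.2, 1 - 3 * (gc - 0.45)^2)
}

#' Simulate windowed read-depth with GC bias and implanted CNVs
#'
#' Raw counts per 300-bp window are negative-binomial around a per-sample
#' mean depth modulated by a GC-bias curve, with windows inside a truth
#' interval scaled by `copy_number / 2`.
#'
#' @param n_windows number of windows on the contig.
#' @param sample_ids character vector of samples.
#' @param seed integer seed.
#' @param gc optional per-window GC fraction (default Uniform(0.25, 0.65)).
#' @param truth optional tibble of [cnv_truth()] rows; intervals may not
#'   overlap within a sample.
#' @param mean_depth mean window count per sample (length 1 or per sample);
#'   the default 100 matches ~30x short-read coverage in 300-bp windows and
#'   puts the normalised per-window noise near sd 0.23.
#' @param dispersion negative-binomial size parameter (larger = tighter).
#' @param gc_bias function mapping GC fraction to a multiplicative factor.
#' @param contig contig name.
#' @return A `coverage_set`: list with `windows` (tibble contig, start, end,
#'   gc, mappable) and `counts` (matrix windows x samples).
#' @export
simulate_coverage <- function(n_windows, sample_ids, seed, gc = NULL,
                              truth = NULL, mean_depth = 100,
                              dispersion = 300, gc_bias = default_gc_bias,
                              contig = "3R") {
  withr_seed(seed)
  if (is.null(gc)) gc <- runif(n_windows, 0.25, 0.65)
  if (any(gc < 0 | gc > 1)) abort("GC fractions must be in [0, 1]")
  N <- length(sample_ids)
  depth <- rep_len(mean_depth, N)
  cn <- matrix(2, nrow = n_windows, ncol = N, dimnames = list(NULL, sample_ids))
  if (!is.null(truth) && nrow(truth)) {
    for (sid in unique(truth$sample_id)) {
      tr <- truth[truth$sample_id == sid, ]
      tr <- tr[order(tr$start_window), ]
      if (nrow(tr) > 1 && any(tr$start_window[-1] <= tr$end_window[-nrow(tr)])) {
        abort(paste0("overlapping truth intervals for sample ", sid))
      }
      for (i in seq_len(nrow(tr))) {
        cn[tr$start_window[i]:tr$end_window[i], sid] <- tr$copy_number[i]
      }
    }
  }
  mu <- sweep(cn / 2 * gc_bias(gc), 2, depth, `*`)
  counts <- matrix(
    rnbinom(n_windows * N, size = dispersion, mu = pmax(mu, 1e-8)),
    nrow = n_windows, dimnames = list(NULL, sample_ids)
  )
  windows <- tibble(
    contig = contig,
    start = seq.int(1L, by = 300L, length.out = n_windows),
    end = seq.int(300L, by = 300L, length.out = n_windows),
    gc = gc,
    mappable = TRUE
  )
  structure(list(windows = windows, counts = counts), class = "coverage_set")
}

#' @export
print.coverage_set <- function(x, ...) {
  cat(sprintf("<coverage_set> %d windows x %d samples\n",
              nrow(x$windows), ncol(x$counts)))
  invisible(x)
}

#' Simulate the full three-taxa study scenario
#'
#' Builds the synthetic analogue of the West-African study design: three
#' diverged taxa (a coluzzii-like "CO", a gambiae-like "GA" and a
#' Bissau-form-like "BIS") at pairwise divergence matched to the
#' interspecific scale (drift F per taxon defaults to 0.03, and under
#' Balding-Nichols the expected pairwise Hudson FST equals F), plus an
#' optional admixed cohort (`alpha` x BIS + (1-alpha) x CO) and an outgroup
#' at larger drift.
#'
#' @param n_variants sites to simulate.
#' @param cohort_size diploids per cohort.
#' @param seed integer seed.
#' @param drift per-taxon drift F; expected pairwise Hudson FST between two
#'   taxa each at drift F is F itself (within-cohort heterozygosity shrinks
#'   by `1 - F` while between-cohort divergence is unchanged).
#' @param admixed_alpha mixing proportion of BIS in the admixed cohort, or
#'   `NULL` to skip it.
#' @param outgroup_drift drift of the outgroup branch, or `NULL` to skip.
#' @param missing_rate genotype missingness rate.
#' @param island_fraction fraction of sites placed in high-divergence
#'   "islands" where drift is `island_drift` instead of `drift`. Real
#'   sibling taxa in this complex differentiate mostly in a few genomic
#'   islands holding near-fixed differences against a low genome-wide
#'   background; the islands are what diagnostic-marker discovery feeds on.
#'   Set to 0 for a uniform-drift genome.
#' @param island_drift drift applied at island sites.
#' @return A list with `geno` (all cohorts column-bound), `meta` (sample
#'   metadata tibble with a `cohort` column), `freqs` (per-cohort
#'   population frequencies), `ancestral`, and `island_sites` (indices).
#' @export
simulate_three_taxa <- function(n_variants = 20000, cohort_size = 50, seed = 1,
                                drift = 0.03, admixed_alpha = 0.5,
                                outgroup_drift = 0.3, missing_rate = 0,
                                island_fraction = 0.02, island_drift = 0.8) {
  taxa <- dplyr::bind_rows(
    taxon_model("CO", drift, cohort_size),
    taxon_model("GA", drift, cohort_size),
    taxon_model("BIS", drift, cohort_size)
  )
  sim <- simulate_frequencies(n_variants, taxa, seed)
  freqs <- sim$freqs
  island_sites <- integer(0)
  if (island_fraction > 0) {
    withr_seed(seed + 77L)
    island_sites <- sort(sample(n_variants, round(island_fraction * n_variants)))
    for (nm in names(freqs)) {
      freqs[[nm]][island_sites] <-
        drift_frequencies(sim$ancestral[island_sites], island_drift)
    }
  }
  if (!is.null(admixed_alpha)) {
    freqs$ADM <- simulate_admixed(freqs$BIS, freqs$CO, admixed_alpha)
  }
  if (!is.null(outgroup_drift)) {
    withr_seed(seed + 101L)
    freqs$OUT <- drift_frequencies(sim$ancestral, outgroup_drift)
  }
  genos <- list()
  meta <- list()
  for (i in seq_along(freqs)) {
    nm <- names(freqs)[i]
    g <- simulate_genotypes(freqs[[i]], cohort_size, seed + 1000L + i,
                            missing_rate = missing_rate,
                            sample_prefix = paste0(nm, "_"))
    genos[[nm]] <- g
    meta[[nm]] <- tibble(sample_id = g$samples, cohort = nm,
                         country = "synthetic", site = "synthetic",
                         sex = "F", year = 2020L)
  }
  calls <- array(
    NA_integer_,
    dim = c(n_variants, cohort_size * length(freqs), 2)
  )
  for (i in seq_along(genos)) {
    cols <- (i - 1L) * cohort_size + seq_len(cohort_size)
    calls[, cols, ] <- genos[[i]]$calls
  }
  g_all <- new_geno(calls, genos[[1]]$variants,
                    unlist(lapply(genos, function(g) g$samples), use.names = FALSE))
  list(geno = g_all, meta = dplyr::bind_rows(meta), freqs = freqs,
       ancestral = sim$ancestral, island_sites = island_sites)
}

#' Write a simulated scenario to standard file formats
#'
#' Emits VCF genotypes, TSV metadata and a BED accessibility mask so the
#' package's own readers can be exercised end-to-end on synthetic data.
#'
#' @param scenario result of [simulate_three_taxa()].
#' @param dir output directory (created if absent).
#' @return Named list of file paths, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    meta = file.path(dir, "samples.tsv"),
    bed = file.path(dir, "accessible.bed")
  )
  write_vcf(scenario$geno, paths$vcf)
  readr::write_tsv(scenario$meta, paths$meta, progress = FALSE)
  ctg <- scenario$geno$variants$contig[1]
  maxpos <- max(scenario$geno$variants$pos)
  writeLines(paste(ctg, 0L, maxpos, sep = "\t"), paths$bed)
  invisible(paths)
}
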
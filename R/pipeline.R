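#' Default pipeline configuration
#'
#' Returns the full parameter set of the end-to-end synthetic run with the
#' study defaults: MAF filter 0.01 (inclusive), optional down-sampling,
#' LD pruning at r-squared 0.01 in 500-SNP windows stepping 250, ten
#' principal components, 1,000-SNP jackknife blocks at desk scale, DAF
#' panel tier `ge85` with 80/20 classification cut-offs, H12 window
#' candidates, and the copy-number HMM defaults.
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    simulate = list(
      n_variants = 20000L, cohort_size = 50L, drift = 0.03,
      admixed_alpha = 0.5, outgroup_drift = 0.3, missing_rate = 0
    ),
    prepare = list(maf_min = 0.01, downsample = NULL),
    prune = list(window_size_snps = 500L, step_snps = 250L,
                 r2_threshold = 0.01, n_iterations = 1L),
    pca = list(n_components = 10L),
    divstats = list(window_accessible_bases = 5000L,
                    cohort_pair = c("BIS", "GA")),
    admixstats = list(block_size_snps = 1000L,
                      f3_target = "ADM", f3_sources = c("BIS", "CO"),
                      d_pops = c("GA", "ADM", "CO", "OUT")),
    daf = list(cohort_a = "BIS", cohort_b = "GA", min_success = 0.10,
               tier = "ge85", hi_cutoff = 80, lo_cutoff = 20),
    h12 = list(n_variants = 4000L, n_haplotypes = 100L,
               window_candidates = c(25L, 50L, 100L, 200L)),
    cnv = list(n_windows = 2000L, n_samples = 10L, min_run = 5L,
               max_state = 12L, n_truth = 8L)
  )
}

validate_config <- function(config) {
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  merged <- utils::modifyList(base, config)
  for (sect in names(base)) {
    if (is.list(base[[sect]]) && !is.null(config[[sect]])) {
      unk <- setdiff(names(config[[sect]]), names(base[[sect]]))
      if (length(unk)) {
        abort(paste0("unknown config key(s) in ", sect, ": ",
                     paste(unk, collapse = ", ")))
      }
    }
  }
  with(merged$prune, {
    if (r2_threshold <= 0 || r2_threshold > 1) {
      abort("prune$r2_threshold must be in (0, 1]")
    }
  })
  if (merged$prepare$maf_min < 0 || merged$prepare$maf_min > 0.5) {
    abort("prepare$maf_min must be in [0, 0.5]")
  }
  merged
}

# deterministic per-stage seed derived from the global seed and stage name
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Run the synthetic analysis pipeline end to end
#'
#' Generates (or accepts) a three-taxa scenario and runs every stage in
#' dependency order: site filtering, LD pruning, PCA, windowed FST/Dxy/
#' diversity, f3 and Patterson's D, DAF panel discovery and individual
#' classification, H12 calibration and scan, and copy-number calling on a
#' simulated coverage track. Each stage's table is written as TSV (when
#' `out_dir` is set) before the next stage begins, together with a JSON
#' run manifest carrying the seed, parameters and a parameter hash, so a
#' re-run with the same config is byte-identical apart from nothing --
#' no timestamps are recorded in outputs.
#'
#' @param config named list as from [default_config()], a YAML file path,
#'   or a partial list merged over the defaults.
#' @param scenario optional pre-built scenario (as from
#'   [simulate_three_taxa()]); by default one is simulated from the
#'   config.
#' @return Named list of stage results (invisibly also written to
#'   `config$out_dir` when set).
#' @export
run_pipeline <- function(config = list(), scenario = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  out <- list(config = cfg)
  emit <- function(name, tbl) {
    if (!is.null(cfg$out_dir) && is.data.frame(tbl)) {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      readr::write_tsv(tbl, file.path(cfg$out_dir, paste0(name, ".tsv")),
                       progress = FALSE)
    }
  }

  # --- data -----------------------------------------------------------
  if (is.null(scenario)) {
    scenario <- do.call(
      simulate_three_taxa,
      c(cfg$simulate, list(seed = stage_seed(cfg$seed, "simulate")))
    )
  }
  g <- scenario$geno
  meta <- scenario$meta

  # --- prepare: site filter + optional down-sampling ------------------
  keep <- filter_sites(g, maf_min = cfg$prepare$maf_min)
  if (!is.null(cfg$prepare$downsample)) {
    keep <- downsample_variants(keep, cfg$prepare$downsample,
                                stage_seed(cfg$seed, "downsample"))
  }
  g <- geno_subset(g, variants = keep)
  out$n_variants_prepared <- n_variants(g)

  # --- prune ----------------------------------------------------------
  dos <- geno_dosage(g)
  keep_ld <- locate_unlinked(dos, do.call(prune_params, cfg$prune))
  g_pruned <- geno_subset(g, variants = keep_ld)
  out$n_variants_pruned <- n_variants(g_pruned)

  # --- structure ------------------------------------------------------
  fit <- pca_patterson(geno_dosage(g_pruned), cfg$pca$n_components)
  out$pca <- fit
  emit("pca_coordinates", tidy(fit))

  # --- divstats -------------------------------------------------------
  ctg <- g$variants$contig[1]
  mask <- stats::setNames(
    list(rep(TRUE, max(g$variants$pos))), ctg
  )
  windows <- accessible_windows(mask, ctg, cfg$divstats$window_accessible_bases)
  pair <- cfg$divstats$cohort_pair
  ac1 <- allele_counts(g, meta$sample_id[meta$cohort == pair[1]])
  ac2 <- allele_counts(g, meta$sample_id[meta$cohort == pair[2]])
  fst <- hudson_fst(ac1, ac2, windows)
  out$fst <- fst
  emit("fst_windows", fst$windows)
  dxy <- dxy_windows(ac1, ac2, windows)
  out$dxy <- dxy
  emit("dxy_windows", dxy)
  div <- diversity_windows(ac1, windows)
  out$diversity <- div
  emit("diversity_windows", div)
  out$sfs <- folded_sfs(ac1)
  emit("folded_sfs", out$sfs)

  # pairwise genome-wide FST matrix over all cohorts
  cohorts <- unique(meta$cohort)
  acs <- lapply(cohorts, function(coh) {
    allele_counts(g, meta$sample_id[meta$cohort == coh])
  })
  names(acs) <- cohorts
  pairs <- utils::combn(cohorts, 2)
  out$fst_matrix <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    tibble(
      cohort_1 = pairs[1, i], cohort_2 = pairs[2, i],
      fst = hudson_fst(acs[[pairs[1, i]]], acs[[pairs[2, i]]])$genome_wide
    )
  })
  emit("fst_matrix", out$fst_matrix)

  # --- admixstats -----------------------------------------------------
  adm <- cfg$admixstats
  if (all(c(adm$f3_target, adm$f3_sources) %in% cohorts)) {
    f3_res <- f3(acs[[adm$f3_target]], acs[[adm$f3_sources[1]]],
                 acs[[adm$f3_sources[2]]], adm$block_size_snps)
  } else {
    f3_res <- NULL
  }
  if (all(adm$d_pops %in% cohorts)) {
    d_res <- patterson_d(acs[[adm$d_pops[1]]], acs[[adm$d_pops[2]]],
                         acs[[adm$d_pops[3]]], acs[[adm$d_pops[4]]],
                         adm$block_size_snps)
  } else {
    d_res <- NULL
  }
  out$admixstats <- bind_rows(f3_res, d_res)
  emit("admixstats", out$admixstats)

  # --- DAF panel + classification -------------------------------------
  daf <- compute_daf(g, meta, cfg$daf$cohort_a, cfg$daf$cohort_b,
                     cfg$daf$min_success)
  panel <- build_panel(daf, cfg$daf$tier)
  out$panel <- panel
  emit("marker_panel", panel)
  ap <- allelic_percentage(g, panel)
  report <- classify_samples(
    ap, cfg$daf$hi_cutoff, cfg$daf$lo_cutoff,
    truth = meta, taxon_a_label = cfg$daf$cohort_a,
    taxon_b_label = cfg$daf$cohort_b
  )
  out$classification <- report
  emit("classification", tidy(report))

  # --- H12 ------------------------------------------------------------
  sweep_cfg <- sweep_config(
    center = cfg$h12$n_variants * 50L, frequency = 0.8,
    flank = cfg$h12$n_variants * 10L
  )
  # window size is calibrated on a neutral track, then the swept track is
  # scanned at the chosen size
  hn <- simulate_haplotypes(cfg$h12$n_variants, cfg$h12$n_haplotypes,
                            stage_seed(cfg$seed, "h12_neutral"))
  cal <- calibrate_window_size(hn$haps, cfg$h12$window_candidates,
                               hn$positions)
  hs <- simulate_haplotypes(cfg$h12$n_variants, cfg$h12$n_haplotypes,
                            stage_seed(cfg$seed, "h12"), sweep = sweep_cfg)
  scan <- scan_h12(hs$haps, hs$positions, cal$window_snps)
  out$h12 <- list(calibration = cal, scan = scan,
                  peaks = find_peaks(scan, 0.1))
  emit("h12_scan", scan)
  emit("h12_peaks", out$h12$peaks)

  # --- CNV ------------------------------------------------------------
  cnv_cfg <- cfg$cnv
  sample_ids <- sprintf("CNV%03d", seq_len(cnv_cfg$n_samples))
  withr_seed(stage_seed(cfg$seed, "cnv_truth"))
  truth <- purrr::map_dfr(seq_len(cnv_cfg$n_truth), function(i) {
    s <- sample(cnv_cfg$n_windows - 20L, 1)
    cnv_truth(sample(sample_ids, 1), "3R", s, s + sample(6:12, 1),
              sample(c(0, 1, 3, 4), 1))
  })
  truth <- truth[!duplicated(truth$sample_id), ]
  cov <- simulate_coverage(cnv_cfg$n_windows, sample_ids,
                           stage_seed(cfg$seed, "cnv"), truth = truth)
  keep_w <- filter_windows(cov)
  tracks <- vapply(sample_ids, function(s) gc_normalize(cov, s, keep_w),
                   numeric(cnv_cfg$n_windows))
  qc <- sample_qc(tracks, keep_w)
  calls <- purrr::map_dfr(sample_ids[qc$qc_pass], function(s) {
    st <- fit_cn_hmm(tracks[, s], keep_w, max_state = cnv_cfg$max_state,
                     sample = s)
    call_cnvs(st, s, min_run = cnv_cfg$min_run)
  })
  out$cnv <- list(truth = truth, calls = calls, qc = qc)
  emit("cnv_calls", calls)
  emit("cnv_truth", truth)

  # --- manifest -------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("cryptaxon")),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), "out_dir")],
    parameter_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  )
  out$manifest <- manifest
  if (!is.null(cfg$out_dir)) {
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(out)
}
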
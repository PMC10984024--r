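#' GC-bias normalisation of windowed coverage
#'
#' Converts one sample's raw window counts to copy-number scale:
#' `2 * count / mean(count)` where the mean is taken over unfiltered
#' autosomal windows in the same GC bin (1-percentage-point bins; bins
#' holding fewer than `min_bin_windows` windows are merged with their
#' neighbour until large enough). A diploid region with the sample's
#' typical depth at its GC content thus normalises to 2.
#'
#' @param cov a `coverage_set` (see [simulate_coverage()] or
#'   [read_coverage_tsv()]).
#' @param sample sample id (column of the counts matrix).
#' @param keep logical keep-mask from [filter_windows()] (default: all).
#' @param autosomal logical vector marking autosomal windows (default: all;
#'   supply `FALSE` for X windows when sexing matters).
#' @param min_bin_windows minimum windows per GC bin before merging.
#' @return Numeric vector of normalised copy number per window (`NA` for
#'   filtered-out windows is *not* applied here; filtering is the HMM's
#'   job).
#' @export
gc_normalize <- function(cov, sample, keep = NULL, autosomal = NULL,
                         min_bin_windows = 100L) {
  counts <- cov$counts[, sample]
  nw <- length(counts)
  if (is.null(keep)) keep <- rep(TRUE, nw)
  if (is.null(autosomal)) autosomal <- rep(TRUE, nw)
  base_idx <- keep & autosomal
  if (sum(counts[base_idx]) == 0) {
    abort(paste0("sample ", sample, " has zero autosomal coverage"))
  }
  bin <- as.integer(round(cov$windows$gc * 100))
  # merge sparse GC bins with their upper neighbour (wrapping down at the top)
  tab <- table(factor(bin[base_idx], levels = sort(unique(bin))))
  levs <- as.integer(names(tab))
  merged <- levs
  counts_per <- as.integer(tab)
  i <- 1L
  while (i <= length(levs)) {
    if (counts_per[i] < min_bin_windows && length(levs) > 1L) {
      j <- if (i < length(levs)) i + 1L else i - 1L
      merged[merged == levs[i]] <- levs[j]
      counts_per[j] <- counts_per[j] + counts_per[i]
      levs <- levs[-i]
      counts_per <- counts_per[-i]
      merged <- merged[merged %in% levs | TRUE]
    } else {
      i <- i + 1L
    }
  }
  bin_map <- stats::setNames(merged, as.character(sort(unique(bin))))
  eff_bin <- bin_map[as.character(bin)]
  means <- tapply(counts[base_idx], eff_bin[base_idx], mean)
  m <- means[as.character(eff_bin)]
  # windows whose GC bin never occurs in the baseline: fall back to the
  # global autosomal mean
  m[is.na(m)] <- mean(counts[base_idx])
  as.numeric(2 * counts / m)
}

#' Window filter for the copy-number HMM
#'
#' Removes windows with extreme GC content or poor mappability from HMM
#' input.
#'
#' @param cov a `coverage_set` with per-window `gc` and `mappable`.
#' @param gc_band inclusive GC band retained (default `c(0.2, 0.8)`).
#' @param min_mappability minimum mappability (the simulator emits a
#'   logical flag; numeric tracks are compared against this threshold).
#' @return Logical keep-mask over windows.
#' @export
filter_windows <- function(cov, gc_band = c(0.2, 0.8), min_mappability = 0.5) {
  ok_gc <- cov$windows$gc >= gc_band[1] & cov$windows$gc <= gc_band[2]
  mp <- cov$windows$mappable
  ok_mp <- if (is.logical(mp)) mp else mp >= min_mappability
  ok_gc & ok_mp
}

# log forward-backward posteriors for the copy-number chain; transition
# matrix is stay = 1 - t, switch = t / (S - 1) shared across states
cn_forward_backward <- function(obs_loglik, stay = 1 - 1e-5) {
  S <- ncol(obs_loglik)
  Tn <- nrow(obs_loglik)
  switch_p <- (1 - stay) / (S - 1)
  la <- matrix(NA_real_, Tn, S)
  lb <- matrix(0, Tn, S)
  la[1, ] <- -log(S) + obs_loglik[1, ]
  for (t in 2:Tn) {
    m <- max(la[t - 1, ])
    w <- exp(la[t - 1, ] - m)
    tot <- sum(w)
    # sum_i w_i A[i,j] = switch * tot + (stay - switch) * w_j
    la[t, ] <- m + log(switch_p * tot + (stay - switch_p) * w) + obs_loglik[t, ]
  }
  for (t in (Tn - 1):1) {
    v <- lb[t + 1, ] + obs_loglik[t + 1, ]
    m <- max(v)
    w <- exp(v - m)
    tot <- sum(w)
    lb[t, ] <- m + log(switch_p * tot + (stay - switch_p) * w)
  }
  lg <- la + lb
  post <- exp(lg - apply(lg, 1, max))
  post / rowSums(post)
}

# Viterbi decode under the same transition structure
cn_viterbi <- function(obs_loglik, stay = 1 - 1e-5) {
  S <- ncol(obs_loglik)
  Tn <- nrow(obs_loglik)
  l_stay <- log(stay)
  l_switch <- log((1 - stay) / (S - 1))
  delta <- matrix(NA_real_, Tn, S)
  psi <- matrix(NA_integer_, Tn, S)
  delta[1, ] <- -log(S) + obs_loglik[1, ]
  for (t in 2:Tn) {
    d <- delta[t - 1, ]
    best <- which.max(d)
    m1 <- d[best]
    d2 <- d
    d2[best] <- -Inf
    second <- which.max(d2)
    m2 <- d2[second]
    # best switching predecessor for state j is the global max unless that
    # max is j itself, in which case the runner-up
    sw_val <- ifelse(seq_len(S) == best, m2, m1)
    sw_arg <- ifelse(seq_len(S) == best, second, best)
    stay_val <- d + l_stay
    use_stay <- stay_val >= sw_val + l_switch
    delta[t, ] <- ifelse(use_stay, stay_val, sw_val + l_switch) + obs_loglik[t, ]
    psi[t, ] <- ifelse(use_stay, seq_len(S), sw_arg)
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta[Tn, ])
  for (t in (Tn - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

#' Gaussian-HMM copy-number state decoding for one sample
#'
#' Hidden states are copy numbers `0 .. max_state` (12 by default).
#' Emissions are Normal with mean `k * baseline / ploidy` for state `k`,
#' where the baseline is the sample's median normalised copy number over
#' unfiltered windows of the contig class (so a typical diploid autosome
#' centres state 2 at its own median), and a shared standard deviation
#' estimated robustly (median absolute deviation of the track, floored to
#' avoid degenerate fits). The transition matrix has a single stay
#' probability (`1 - 1e-5` by default) shared by all states with the
#' complement spread evenly, encoding that copy-number changes are rare.
#' States are decoded by the most likely (Viterbi) path; per-window
#' posteriors of the decoded state come from forward-backward.
#'
#' @param track normalised copy-number vector from [gc_normalize()].
#' @param keep logical keep-mask from [filter_windows()]; filtered windows
#'   are excluded from the chain and reported with `NA` state.
#' @param sex `"F"`, `"M"` or `"unknown"`; with `contig_is_x = TRUE` and a
#'   male sample, ploidy is 1.
#' @param contig_is_x is this contig the X chromosome?
#' @param max_state largest copy-number state.
#' @param stay transition stay-probability.
#' @param min_sd floor for the emission standard deviation.
#' @param sample label used in error messages.
#' @return Tibble with `window`, `state` (`NA` where filtered), and
#'   `posterior` (posterior probability of the decoded state).
#' @export
fit_cn_hmm <- function(track, keep = NULL, sex = "F", contig_is_x = FALSE,
                       max_state = 12L, stay = 1 - 1e-5, min_sd = 0.1,
                       sample = "sample") {
  nw <- length(track)
  if (is.null(keep)) keep <- rep(TRUE, nw)
  idx <- which(keep & is.finite(track))
  if (length(idx) < 5) abort(paste0("fewer than 5 usable windows for ", sample))
  x <- track[idx]
  ploidy <- if (contig_is_x && identical(sex, "M")) 1L else 2L
  baseline <- median(x)
  if (!is.finite(baseline) || baseline <= 0) {
    abort(paste0("degenerate baseline for sample ", sample))
  }
  sdev <- max(mad(x), min_sd)
  if (!is.finite(sdev) || sdev <= 0) {
    abort(paste0("degenerate emission variance for sample ", sample))
  }
  states <- 0:max_state
  means <- states * baseline / ploidy
  ll <- vapply(means, function(m) stats::dnorm(x, m, sdev, log = TRUE),
               numeric(length(x)))
  ll <- matrix(ll, ncol = length(states))
  path <- cn_viterbi(ll, stay)
  post <- cn_forward_backward(ll, stay)
  state <- rep(NA_integer_, nw)
  posterior <- rep(NA_real_, nw)
  state[idx] <- states[path]
  posterior[idx] <- post[cbind(seq_along(path), path)]
  tibble(window = seq_len(nw), state = state, posterior = posterior)
}

#' Call copy-number variants from decoded states
#'
#' Maximal runs of adjacent decoded windows with state above ploidy
#' (amplifications) or below ploidy (deletions), where ploidy is 2 on
#' autosomes and 1 for males on the X. Runs shorter than `min_run`
#' windows are discarded; runs whose mean decoded-state posterior falls
#' below `min_posterior` are retained but flagged (`qc_pass = FALSE`) and
#' excluded from cohort frequencies. Filtered (`NA`-state) windows break
#' adjacency.
#'
#' @param states tibble from [fit_cn_hmm()].
#' @param sample_id sample label for the calls.
#' @param contig contig label.
#' @param sex,contig_is_x as in [fit_cn_hmm()].
#' @param min_run minimum run length in windows (default 5).
#' @param min_posterior minimum mean posterior for a quality call.
#' @return Tibble of calls: `sample_id`, `contig`, `start_window`,
#'   `end_window`, `n_windows`, `type` (`"amp"`/`"del"`), `modal_state`,
#'   `mean_posterior`, `qc_pass`.
#' @export
call_cnvs <- function(states, sample_id, contig = "3R", sex = "F",
                      contig_is_x = FALSE, min_run = 5L, min_posterior = 0.9) {
  ploidy <- if (contig_is_x && identical(sex, "M")) 1L else 2L
  st <- states$state
  cls <- ifelse(is.na(st), "na", ifelse(st > ploidy, "amp",
                ifelse(st < ploidy, "del", "normal")))
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values %in% c("amp", "del") & r$lengths >= min_run)
  if (!length(sel)) {
    return(tibble(sample_id = character(), contig = character(),
                  start_window = integer(), end_window = integer(),
                  n_windows = integer(), type = character(),
                  modal_state = integer(), mean_posterior = double(),
                  qc_pass = logical()))
  }
  purrr::map_dfr(sel, function(k) {
    i <- starts[k]:ends[k]
    tabst <- table(st[i])
    tibble(
      sample_id = sample_id,
      contig = contig,
      start_window = starts[k],
      end_window = ends[k],
      n_windows = length(i),
      type = r$values[k],
      modal_state = as.integer(names(tabst)[which.max(tabst)]),
      mean_posterior = mean(states$posterior[i]),
      qc_pass = mean(states$posterior[i]) >= min_posterior
    )
  })
}

#' Per-sample coverage-variance quality control
#'
#' Samples whose normalised copy-number variance over unfiltered autosomal
#' windows exceeds the threshold are flagged and should be excluded from
#' calling and cohort frequencies.
#'
#' @param tracks named list (or matrix columns) of normalised tracks.
#' @param keep logical keep-mask over windows.
#' @param max_variance QC threshold (default 0.2).
#' @return Tibble `sample_id`, `variance`, `qc_pass`.
#' @export
sample_qc <- function(tracks, keep = NULL, max_variance = 0.2) {
  if (is.matrix(tracks)) {
    tracks <- stats::setNames(
      lapply(seq_len(ncol(tracks)), function(i) tracks[, i]),
      colnames(tracks)
    )
  }
  purrr::imap_dfr(tracks, function(tr, sid) {
    k <- if (is.null(keep)) rep(TRUE, length(tr)) else keep
    v <- var(tr[k], na.rm = TRUE)
    tibble(sample_id = sid, variance = v, qc_pass = is.finite(v) & v <= max_variance)
  })
}

#' Cohort CNV frequencies over named gene regions
#'
#' For each cohort x region x call type, the fraction of QC-passing
#' individuals carrying at least one quality call overlapping the region.
#' An individual with several overlapping calls counts once (the
#' frequency is presence/absence, not copy count).
#'
#' @param calls call tibble from [call_cnvs()] (rows from all samples).
#' @param regions tibble `region`, `contig`, `start_window`, `end_window`.
#' @param meta metadata tibble (`sample_id`, `cohort`) restricted to
#'   QC-passing samples.
#' @param contigs optional character vector of known contigs; a region on
#'   a contig outside this set raises an error.
#' @return Tibble `cohort`, `region`, `type`, `n_carriers`, `n_samples`,
#'   `frequency`.
#' @export
cohort_cnv_frequency <- function(calls, regions, meta, contigs = NULL) {
  if (!is.null(contigs)) {
    miss <- setdiff(regions$contig, contigs)
    if (length(miss)) {
      abort(paste0("region contig(s) absent from data: ",
                   paste(miss, collapse = ", ")))
    }
  }
  good <- calls %>% filter(.data$qc_pass)
  grid <- tidyr::expand_grid(
    meta %>% distinct(.data$cohort),
    regions %>% select("region", "contig", "start_window", "end_window"),
    type = c("amp", "del")
  )
  purrr::pmap_dfr(
    grid,
    function(cohort, region, contig, start_window, end_window, type) {
      members <- meta$sample_id[meta$cohort == cohort]
      hit <- good %>%
        filter(.data$type == !!type, .data$contig == !!contig,
               .data$sample_id %in% members,
               .data$start_window <= !!end_window,
               .data$end_window >= !!start_window)
      tibble(
        cohort = cohort, region = region, type = type,
        n_carriers = dplyr::n_distinct(hit$sample_id),
        n_samples = length(members),
        frequency = if (length(members)) {
          dplyr::n_distinct(hit$sample_id) / length(members)
        } else NA_real_
      )
    }
  )
}

#' Read a windowed coverage table
#'
#' TSV with columns `contig`, `start`, `end`, `gc`, `mappable`, then one
#' column of raw counts per sample.
#'
#' @param path TSV path.
#' @return A `coverage_set`.
#' @export
read_coverage_tsv <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  req <- c("contig", "start", "end", "gc", "mappable")
  if (!all(req %in% names(d))) abort("coverage TSV lacks required columns")
  counts <- as.matrix(d[setdiff(names(d), req)])
  structure(
    list(windows = d[req], counts = counts),
    class = "coverage_set"
  )
}
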
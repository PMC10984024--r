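test_that("GC normalisation removes imposed bias and preserves implanted copy number", {
  # uniform coverage, uniform GC -> CN = 2 everywhere
  sids <- "s1"
  cov <- simulate_coverage(3000, sids, seed = 81, gc = rep(0.45, 3000))
  tr <- gc_normalize(cov, "s1")
  expect_lt(abs(mean(tr) - 2), 0.05)
  expect_lt(stats::sd(tr), 0.5)
  # quadratic GC bias, no CNVs: per-bin mean CN back to 2 +/- 0.05
  set.seed(82)
  gc <- runif(20000, 0.25, 0.65)
  cov2 <- simulate_coverage(20000, sids, seed = 83, gc = gc)
  tr2 <- gc_normalize(cov2, "s1")
  bins <- cut(gc, seq(0.25, 0.65, by = 0.05))
  bin_means <- tapply(tr2, bins, mean)
  expect_true(all(abs(bin_means - 2) < 0.05))
  # implanted CN = 4 segment survives normalisation
  truth <- cnv_truth("s1", "3R", 501, 520, 4)
  cov3 <- simulate_coverage(5000, sids, seed = 84, truth = truth)
  tr3 <- gc_normalize(cov3, "s1")
  expect_lt(abs(mean(tr3[501:520]) - 4), 0.4)
  # zero coverage -> QC fail error
  cov0 <- cov
  cov0$counts[, 1] <- 0L
  expect_error(gc_normalize(cov0, "s1"), "zero autosomal coverage")
})

test_that("window filtering drops extreme GC and unmappable windows", {
  cov <- simulate_coverage(100, "s", seed = 85,
                           gc = c(0.9, rep(0.45, 98), 0.1))
  cov$windows$mappable[50] <- FALSE
  keep <- filter_windows(cov)
  expect_false(keep[1])
  expect_false(keep[100])
  expect_false(keep[50])
  expect_equal(sum(keep), 97)
})

test_that("Viterbi decoding equals brute-force max-product on small tracks", {
  set.seed(86)
  enumerate_best <- function(ll, stay) {
    S <- ncol(ll)
    Tn <- nrow(ll)
    paths <- as.matrix(expand.grid(rep(list(seq_len(S)), Tn)))
    l_stay <- log(stay)
    l_switch <- log((1 - stay) / (S - 1))
    best <- -Inf
    best_path <- NULL
    for (r in seq_len(nrow(paths))) {
      pth <- paths[r, ]
      lp <- -log(S) + sum(ll[cbind(seq_len(Tn), pth)]) +
        sum(ifelse(diff(pth) == 0, l_stay, l_switch))
      if (lp > best) {
        best <- lp
        best_path <- pth
      }
    }
    best_path
  }
  for (rep_i in 1:5) {
    Tn <- sample(6:10, 1)
    S <- 4
    ll <- matrix(rnorm(Tn * S, sd = 2), Tn, S)
    vit <- cryptaxon:::cn_viterbi(ll, stay = 0.9)
    expect_equal(vit, unname(enumerate_best(ll, 0.9)))
  }
})

test_that("the copy-number HMM decodes flat tracks and implanted segments", {
  set.seed(87)
  flat <- rnorm(500, 2, 0.1)
  st <- fit_cn_hmm(flat)
  expect_true(all(st$state == 2L))
  # implanted 10-window segment at 4.0 with sd 0.25
  seg <- flat
  seg[201:210] <- rnorm(10, 4, 0.25)
  st2 <- fit_cn_hmm(seg)
  expect_true(all(st2$state[201:210] == 4L))
  expect_true(all(st2$state[-(201:210)] == 2L))
  # male X at 1.0 -> all states 1 under ploidy 1
  x <- rnorm(500, 1, 0.1)
  stx <- fit_cn_hmm(x, sex = "M", contig_is_x = TRUE)
  expect_true(all(stx$state == 1L))
})

test_that("CNV calls enforce the 5-window run rule and the sex-aware threshold", {
  mk_states <- function(states) {
    tibble::tibble(window = seq_along(states), state = states,
                   posterior = 0.99)
  }
  # 4 amplified windows -> no call
  s4 <- mk_states(c(rep(2L, 10), rep(3L, 4), rep(2L, 10)))
  expect_equal(nrow(call_cnvs(s4, "s")), 0)
  # 5 windows at state 3 -> one amplification call
  s5 <- mk_states(c(rep(2L, 10), rep(3L, 5), rep(2L, 10)))
  calls <- call_cnvs(s5, "s")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$type, "amp")
  expect_equal(calls$start_window, 11L)
  expect_equal(calls$n_windows, 5L)
  # male X: 6-window run at state 2 is an amplification (threshold > 1)
  sx <- mk_states(c(rep(1L, 10), rep(2L, 6), rep(1L, 10)))
  callx <- call_cnvs(sx, "s", sex = "M", contig_is_x = TRUE)
  expect_equal(nrow(callx), 1)
  expect_equal(callx$type, "amp")
  # deletions called symmetrically
  sdel <- mk_states(c(rep(2L, 10), rep(0L, 6), rep(2L, 10)))
  expect_equal(call_cnvs(sdel, "s")$type, "del")
  # low-posterior runs flagged
  slow <- mk_states(c(rep(2L, 10), rep(3L, 6), rep(2L, 10)))
  slow$posterior[11:16] <- 0.5
  expect_false(call_cnvs(slow, "s")$qc_pass)
})

test_that("sample QC thresholds coverage variance", {
  set.seed(88)
  tracks <- list(
    good = rnorm(1000, 2, 0.1),
    bad = rnorm(1000, 2, 0.75)
  )
  qc <- sample_qc(tracks)
  expect_true(qc$qc_pass[qc$sample_id == "good"])
  expect_false(qc$qc_pass[qc$sample_id == "bad"])
  # configurable threshold
  qc2 <- sample_qc(tracks, max_variance = 1)
  expect_true(all(qc2$qc_pass))
})

test_that("cohort frequencies are presence/absence based and order-invariant", {
  calls <- tibble::tibble(
    sample_id = c("a", "a", "b", "c"),
    contig = "3R",
    start_window = c(10L, 100L, 12L, 500L),
    end_window = c(20L, 110L, 22L, 520L),
    n_windows = 11L, type = "amp", modal_state = 4L,
    mean_posterior = 0.99, qc_pass = c(TRUE, TRUE, TRUE, FALSE)
  )
  regions <- tibble::tibble(region = "geneX", contig = "3R",
                            start_window = 15L, end_window = 18L)
  meta <- tibble::tibble(sample_id = c("a", "b", "c", "d"), cohort = "pop1")
  fr <- cohort_cnv_frequency(calls, regions, meta)
  amp <- fr[fr$type == "amp", ]
  # a (twice overlapping counts once) and b overlap; c fails call QC; d no call
  expect_equal(amp$frequency, 2 / 4)
  # no calls -> all zero
  fr0 <- cohort_cnv_frequency(calls[0, ], regions, meta)
  expect_true(all(fr0$frequency == 0))
  # shuffled calls give identical frequencies
  fr_shuffled <- cohort_cnv_frequency(calls[c(4, 2, 1, 3), ], regions, meta)
  expect_equal(fr, fr_shuffled)
  # region on unknown contig errors when contigs are declared
  bad_regions <- dplyr::mutate(regions, contig = "nope")
  expect_error(cohort_cnv_frequency(calls, bad_regions, meta, contigs = "3R"),
               "absent")
})

test_that("end-to-end CNV recovery finds implanted duplications", {
  set.seed(89)
  n_win <- 1500
  sids <- sprintf("S%02d", 1:8)
  truth <- purrr::map_dfr(seq_along(sids), function(i) {
    s <- 150 * i
    cnv_truth(sids[i], "3R", s, s + 7 + (i %% 4), sample(3:6, 1))
  })
  cov <- simulate_coverage(n_win, sids, seed = 90, truth = truth)
  keep <- filter_windows(cov)
  calls <- purrr::map_dfr(sids, function(s) {
    tr <- gc_normalize(cov, s, keep)
    call_cnvs(fit_cn_hmm(tr, keep, sample = s), s)
  })
  hits <- sum(purrr::map_lgl(seq_len(nrow(truth)), function(i) {
    any(calls$sample_id == truth$sample_id[i] &
          calls$start_window <= truth$end_window[i] &
          calls$end_window >= truth$start_window[i] &
          calls$type == "amp")
  }))
  expect_equal(hits, nrow(truth))
  # no spurious extra calls
  fp <- sum(purrr::map_lgl(seq_len(nrow(calls)), function(i) {
    !any(truth$sample_id == calls$sample_id[i] &
           truth$start_window <= calls$end_window[i] &
           truth$end_window >= calls$start_window[i])
  }))
  expect_equal(fp, 0)
})
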
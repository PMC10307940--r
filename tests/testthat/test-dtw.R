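# The dwell-constrained alignment dynamic program, Welch's t, adaptive
# window detection, and the two-pass per-read estimator.

test_that("degenerate single-state alignment has zero cost", {
  aut <- toy_automaton(levels = 0.7, edges = list(), start = 1, accept = 1)
  al <- align_signal(rep(0.7, 10), aut, dwell_policy(4L))
  expect_equal(al$cost, 0)
  expect_equal(al$path_states, rep(1L, 10))
})

test_that("a 3-state chain with exactly met dwell aligns at zero cost", {
  aut <- toy_automaton(levels = c(-1, 0, 1),
                       edges = list(c(1L, 2L), c(2L, 3L)),
                       start = 1, accept = 3)
  sig <- rep(c(-1, 0, 1), each = 4)
  al <- align_signal(sig, aut, dwell_policy(4L))
  expect_equal(al$cost, 0)
  expect_equal(al$path_states, rep(1:3, each = 4))
  runs <- rle(al$path_states)
  expect_equal(length(runs$values) - 1L, 2L)  # two transitions
})

test_that("infeasible alignments raise a classed rejection", {
  aut <- toy_automaton(levels = c(-1, 0, 1),
                       edges = list(c(1L, 2L), c(2L, 3L)),
                       start = 1, accept = 3)
  err <- tryCatch(align_signal(rep(0, 10), aut, dwell_policy(4L)),
                  warp_reject = identity)
  expect_s3_class(err, "alignment_infeasible")
})

test_that("DP cost equals the brute-force oracle on a randomized grid", {
  set.seed(303)
  n_checked <- 0L
  for (rep_i in 1:12) {
    n_states <- sample(3:6, 1)
    aut <- random_toy_automaton(n_states, extra_edges = sample(0:2, 1))
    for (s in c(1L, 2L, 4L)) {
      m <- sample(seq(n_states * s, 30), 1)
      sig <- round(runif(m, -2, 2), 3)
      oracle <- oracle_align_cost(sig, aut, s)
      got <- tryCatch(align_signal(sig, aut, dwell_policy(s))$cost,
                      warp_reject = function(e) Inf)
      expect_equal(got, oracle, tolerance = 1e-9,
                   info = sprintf("states=%d s=%d m=%d", n_states, s, m))
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 30L)
})

test_that("DP handles the anchored counterexample the same as brute force", {
  # appending a point CAN decrease the anchored optimal cost; both the DP
  # and the oracle must agree on it
  aut <- toy_automaton(levels = c(0, 10, 0),
                       edges = list(c(1L, 2L), c(2L, 3L)),
                       start = 1, accept = 3)
  sig3 <- c(0, 0, 10)
  sig4 <- c(0, 0, 10, 0)
  c3 <- align_signal(sig3, aut, dwell_policy(1L))$cost
  c4 <- align_signal(sig4, aut, dwell_policy(1L))$cost
  expect_equal(c3, oracle_align_cost(sig3, aut, 1L))
  expect_equal(c4, oracle_align_cost(sig4, aut, 1L))
  expect_lt(c4, c3)
})

test_that("no returned run is shorter than its effective minimum dwell", {
  set.seed(404)
  for (i in 1:10) {
    aut <- random_toy_automaton(sample(4:7, 1), extra_edges = 1L)
    s <- sample(2:4, 1)
    m <- sample((nrow(aut$states) * s):40, 1)
    sig <- round(runif(m, -2, 2), 3)
    al <- tryCatch(align_signal(sig, aut, dwell_policy(s)),
                   warp_reject = function(e) NULL)
    if (is.null(al)) next
    runs <- rle(al$path_states)
    expect_true(all(runs$lengths >= s), info = paste("s =", s))
    # consecutive path states obey the transition relation
    froms <- runs$values[-length(runs$values)]
    tos <- runs$values[-1]
    key <- paste(aut$trans$from, aut$trans$to)
    expect_true(all(paste(froms, tos) %in% key))
  }
})

test_that("window overrides lower the dwell floor where they apply", {
  aut <- toy_automaton(levels = c(-1, 0, 1),
                       edges = list(c(1L, 2L), c(2L, 3L)),
                       start = 1, accept = 3)
  # middle event has only 3 points: s = 4 must borrow a mismatched point
  sig <- c(rep(-1, 5), rep(0, 3), rep(1, 5))
  al4 <- align_signal(sig, aut, dwell_policy(4L))
  expect_gt(al4$cost, 0)
  expect_false(identical(rle(al4$path_states)$lengths, c(5L, 3L, 5L)))
  pol <- dwell_policy(4L, overrides = data.frame(start = 6, end = 8, s = 3))
  al <- align_signal(sig, aut, pol)
  expect_equal(al$cost, 0)
  expect_equal(rle(al$path_states)$lengths, c(5L, 3L, 5L))
  # a genuinely infeasible case: fewer points than states x minimum dwell
  expect_s3_class(tryCatch(align_signal(sig[1:10], aut, dwell_policy(4L)),
                           warp_reject = identity),
                  "alignment_infeasible")
})

test_that("welch_t matches the spec'd conventions and the oracle", {
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(welch_t(c(1, 1, 1, 1), c(2, 2, 2, 2)), -Inf)
  expect_equal(welch_t(c(2, 2), c(1, 1)), Inf)
  expect_equal(welch_t(c(5, 5, 5), c(5, 5, 5)), 0)
  s1 <- c(0, 1, 0, 1)
  s2 <- c(1, 2, 1, 2)
  expect_equal(welch_t(s1, s2), oracle_welch(s1, s2))
  expect_equal(welch_t(s1, s2), -1 / sqrt(0.5 / 4))
  set.seed(505)
  for (i in 1:20) {
    p <- sample(2:8, 1)
    a <- rnorm(p); b <- rnorm(p, 1)
    expect_equal(welch_t(a, b), oracle_welch(a, b))
  }
  expect_error(welch_t(1:3, 1:4), "equal length")
})

test_that("short-event window detection flags planted context changes", {
  # build a fake alignment: 12 events of 8 points each -> 2 windows
  states <- rep(1:12, each = 8)
  sig_const <- rep(0, 96)
  al_const <- structure(list(cost = 0, path_states = states,
                             signal = sig_const, sreq = rep(4L, 96)),
                        class = "warp_alignment")
  win <- detect_short_event_windows(al_const, m_events = 6L, p = 3L)
  expect_equal(nrow(win), 2L)  # ceil(12 / 6)
  expect_equal(win$n_events, c(6L, 6L))
  expect_equal(win$n_peaks, c(0L, 0L))
  expect_false(any(win$override))

  # plant 8 sharp level shifts strictly inside the first 48-point window
  # (a shift at the window edge is invisible to the sliding statistic)
  sig <- sig_const
  bounds <- seq(5, by = 5, length.out = 8)
  lv <- rep(c(0, 2), length.out = 9)
  sig[1:48] <- rep(lv, times = diff(c(0, bounds, 48)))[1:48]
  al <- structure(list(cost = 0, path_states = states, signal = sig,
                       sreq = rep(4L, 96)),
                  class = "warp_alignment")
  win2 <- detect_short_event_windows(al, m_events = 6L, p = 3L)
  expect_equal(win2$n_peaks[1], 8L)
  expect_true(win2$override[1])
  expect_equal(win2$s[1], 3L)
  expect_false(win2$override[2])

  # windows shorter than 2p are skipped
  al_short <- structure(list(cost = 0, path_states = rep(1:2, each = 2),
                             signal = rep(0, 4), sreq = rep(1L, 4)),
                        class = "warp_alignment")
  win3 <- detect_short_event_windows(al_short, m_events = 6L, p = 3L)
  expect_true(is.na(win3$n_peaks[1]))
  expect_false(win3$override[1])
})

test_that("windows partition the events", {
  read <- sim_locus_read(count = 10L, seed = 66L)
  ka <- test_automaton()
  seg <- extract_signal_segment(read, c(1, nchar(read$basecall)))
  al <- align_signal(normalize_median(seg), ka, dwell_policy(4L))
  n_events <- length(rle(al$path_states)$values)
  win <- detect_short_event_windows(al, m_events = 6L, p = 3L)
  expect_equal(nrow(win), ceiling(n_events / 6))
  expect_equal(sum(win$n_events), n_events)
  expect_equal(win$start[1], 1L)
  expect_equal(win$end[nrow(win)], length(al$signal))
})

test_that("ideal signal with dwell exactly 4 aligns at cost ~0, exact length", {
  model <- test_model()
  flanks <- test_flanks()
  ka <- test_automaton("(CAG)", flanks, model)
  for (count in c(5L, 12L)) {
    seq_full <- paste0(flanks$left, strrep("CAG", count), flanks$right)
    n_kmers <- nchar(seq_full) - 2L
    kmers <- substring(seq_full, seq_len(n_kmers), seq_len(n_kmers) + 2L)
    ideal <- rep(unname(model$levels[kmers]), each = 4L)
    al <- align_signal(ideal, ka, dwell_policy(4L))
    expect_equal(al$cost, 0)
    cc <- count_str_length(al, ka)
    expect_equal(cc$length, 3L * count)
    expect_equal(unname(cc$group_counts["0"]), count)
  }
})

test_that("two-pass estimation recovers planted lengths at zero noise", {
  ka <- test_automaton()
  cfg0 <- sim_config(k = 3L, noise_sd = 0, flank_length = 30L)
  errs <- vapply(1:6, function(seed) {
    read <- sim_locus_read(count = 10L, config = cfg0, seed = seed)
    seg <- extract_signal_segment(read, c(1, nchar(read$basecall)))
    run_two_pass(seg, ka)$final_length - 30L
  }, 0L)
  expect_equal(median(abs(errs)), 0)
})

test_that("per-group counts split repeats and interruptions", {
  model <- test_model()
  flanks <- test_flanks()
  base <- build_base_automaton("(CAGG{CAGA})", flanks$left, flanks$right,
                               k = 3)
  ka <- expand_to_kmer_automaton(base, model)
  # one interrupted traversal among three: CAGG CAGA CAGG
  str_seq <- "CAGGCAGACAGG"
  full <- paste0(flanks$left, str_seq, flanks$right)
  cfg <- sim_config(k = 3L, noise_sd = 0, flank_length = 30L)
  read <- squiggleSTR:::with_local_seed(7L,
    simulate_read(full, model, cfg, "dm2"))
  seg <- extract_signal_segment(read, c(1, nchar(read$basecall)))
  res <- run_two_pass(seg, ka)
  expect_equal(res$final_length, nchar(str_seq))
  expect_equal(unname(res$final$group_counts["0"]), 2L)
  expect_equal(unname(res$final$optional_counts["0"]), 1L)
})

test_that("parameter recovery: median absolute length error is zero", {
  ka <- test_automaton()
  cfg <- sim_config(k = 3L, flank_length = 30L)  # default moderate noise
  errs <- integer(0)
  for (count in c(5L, 20L)) {
    for (seed in 1:8) {
      read <- sim_locus_read(count = count, config = cfg,
                             seed = 1000L + 7L * seed + count)
      seg <- extract_signal_segment(read, c(1, nchar(read$basecall)))
      res <- run_two_pass(seg, ka)
      errs <- c(errs, res$final_length - 3L * count)
    }
  }
  expect_equal(median(abs(errs)), 0)
})

test_that("a miscalibration-induced spurious repeat disappears after polishing", {
  fx <- spurious_repeat_fixture()
  res <- run_two_pass(fx$segment, fx$kaut)
  expect_gt(res$pass1_length, fx$truth_length)      # spurious extra repeat
  expect_equal(res$final_length, fx$truth_length)   # corrected by polishing
  expect_equal(unname(res$final$group_counts["0"]), fx$truth_groups)
  expect_lt(res$cost2, res$cost1)
})
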
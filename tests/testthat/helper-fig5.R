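# Crafted spurious-repeat fixture: an ideal zero-noise (CAG)x10 read in
# which one CAG event carries a small wobble (+/- <= 0.08 in model units),
# passed through a monotone piecewise-linear miscalibration that is steep
# around the CAG level.  Pre-polish, the miscalibration blasts the wobble
# out to the exact AGC/GCA/CAG cycle levels, so the first alignment pass
# walks one spurious extra repeat; the polishing spline learned from the
# rest of the read compresses the wobble back and the second pass drops
# the extra repeat.  Everything is deterministic.
spurious_repeat_fixture <- function() {
  model <- make_synthetic_pore_model(3, seed = 7)
  fl <- test_flanks()
  base <- build_base_automaton("(CAG)", fl$left, fl$right, k = 3)
  kaut <- expand_to_kmer_automaton(base, model)
  lv <- model$levels
  e_agc <- unname(lv["AGC"])
  e_gca <- unname(lv["GCA"])
  e_cag <- unname(lv["CAG"])

  count <- 10L
  seqfull <- paste0(fl$left, strrep("CAG", count), fl$right)
  n_kmers <- nchar(seqfull) - 2L
  kmers <- substring(seqfull, 1:n_kmers, 3:(n_kmers + 2))
  dwell <- 6L
  v1 <- e_cag - 0.06
  v2 <- e_cag + 0.08

  cag_events <- which(kmers == "CAG")
  ev <- cag_events[cag_events > nchar(fl$left)][6]
  event_vals <- lapply(seq_len(n_kmers), function(i) {
    if (i == ev) {
      c(rep(unname(lv[kmers[i]]), 4), rep(v1, 4), rep(v2, 4),
        rep(unname(lv[kmers[i]]), 6))
    } else {
      rep(unname(lv[kmers[i]]), dwell)
    }
  })
  true_vals <- unlist(event_vals)

  xs <- c(-2.6, e_agc, v1, e_cag, v2, e_gca, 2.6)
  ys <- c(-2.9, e_agc - 0.30, e_agc, e_cag, e_gca, e_gca + 0.30, 2.9)
  stopifnot(!is.unsorted(xs), !is.unsorted(ys))
  miscal <- approxfun(xs, ys, rule = 2)

  list(
    segment = miscal(true_vals) * 10 + 80,  # arbitrary raw scale/shift
    kaut = kaut,
    truth_length = 3L * count,
    truth_groups = count
  )
}
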
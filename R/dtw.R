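# Signal-to-automaton alignment: the dwell-constrained DTW dynamic
# program, repeat-length counting from the warping path, and the adaptive
# event-size restriction driven by Welch's t statistic.

#' Dwell policy for the alignment dynamic program
#'
#' @param default minimum number of signal points per state (the event-size
#'   floor `s`)
#' @param overrides optional data.frame with columns `start`, `end`, `s`:
#'   runs starting within `[start, end]` (signal indices) use the override
#'   minimum instead
#' @return an object of class `dwell_policy`
#' @export
dwell_policy <- function(default = 4L, overrides = NULL) {
  default <- as.integer(default)
  if (default < 1L) stop("minimum dwell must be >= 1")
  if (!is.null(overrides)) {
    stopifnot(all(c("start", "end", "s") %in% names(overrides)))
    if (any(overrides$s < 1L)) stop("all dwell minimums must be >= 1")
  }
  structure(list(default = default, overrides = overrides),
            class = "dwell_policy")
}

# materialize the per-signal-index dwell requirement vector
dwell_requirements <- function(policy, m) {
  sreq <- rep(policy$default, m)
  ov <- policy$overrides
  if (!is.null(ov) && nrow(ov) > 0L) {
    for (r in seq_len(nrow(ov))) {
      lo <- max(1L, as.integer(ov$start[r]))
      hi <- min(m, as.integer(ov$end[r]))
      if (lo <= hi) sreq[lo:hi] <- as.integer(ov$s[r])
    }
  }
  sreq
}

#' Align a normalized signal to a k-mer automaton
#'
#' Finds the minimum-cost warping path from the automaton's start state at
#' the first signal point to an accept state at the last, where the cost
#' of aligning point `i` to state `j` is `|s_i - e_j|` and every maximal
#' run of one state must contain at least the policy's minimum number of
#' points.  Ties prefer staying in the current state, then predecessors in
#' lexicographic k-mer order, so paths are deterministic.
#'
#' @param signal a `normalized_signal` or plain numeric vector on the
#'   pore-model scale
#' @param kaut a `kmer_automaton`
#' @param policy a `dwell_policy` (or a single integer minimum dwell)
#' @return an object of class `warp_alignment` with fields `cost`,
#'   `path_states` (aligned state id per signal point), `signal`, `sreq`
#' @export
align_signal <- function(signal, kaut, policy = dwell_policy(4L)) {
  if (inherits(signal, "normalized_signal")) signal <- signal$values
  if (!inherits(policy, "dwell_policy")) policy <- dwell_policy(policy)
  stopifnot(inherits(kaut, "kmer_automaton"))
  m <- length(signal)
  sreq <- dwell_requirements(policy, m)
  pred0 <- lapply(kaut$pred, function(p) as.integer(p) - 1L)
  res <- dtw_align_cpp(as.numeric(signal), kaut$states$level, pred0,
                       as.integer(kaut$start) - 1L,
                       as.integer(kaut$accept) - 1L,
                       as.integer(sreq))
  if (!isTRUE(res$feasible)) {
    stop(warp_reject(
      "alignment infeasible: signal too short for the dwell constraints",
      "alignment_infeasible"
    ))
  }
  structure(
    list(cost = res$cost, path_states = res$path, signal = as.numeric(signal),
         sreq = sreq),
    class = "warp_alignment"
  )
}

#' @export
print.warp_alignment <- function(x, ...) {
  cat("<warp_alignment> ", length(x$signal), " points over ",
      length(unique(x$path_states)), " states; cost = ",
      signif(x$cost, 6), "\n", sep = "")
  invisible(x)
}

# maximal runs of one state along the warping path
path_runs <- function(alignment) {
  st <- alignment$path_states
  r <- rle(st)
  ends <- cumsum(r$lengths)
  data.frame(state = r$values,
             start = ends - r$lengths + 1L,
             end = ends,
             length = r$lengths)
}

#' Read the STR length and per-group repeat counts off a warping path
#'
#' The length in bases equals the number of state transitions whose
#' destination state belongs to the repeat region (one transition per
#' consumed repeat base, the flanks contributing nothing).  Per-group
#' counts are the numbers of completed traversals of each repeat group's
#' entry boundary, and interruption counts the traversals of each optional
#' block's entry.
#'
#' @param alignment a `warp_alignment`
#' @param kaut the `kmer_automaton` it was computed against
#' @return list with `length` (integer, bases), `group_counts` and
#'   `optional_counts` (named integer vectors by group / block id)
#' @export
count_str_length <- function(alignment, kaut) {
  runs <- path_runs(alignment)
  dest <- runs$state[-1]  # destinations of the transitions between runs
  len <- sum(kaut$states$role[dest] == "repeat")

  gc <- integer(max(kaut$n_groups, 0L))
  if (kaut$n_groups > 0L) {
    names(gc) <- as.character(seq_len(kaut$n_groups) - 1L)
    eg <- kaut$entry_group[dest]
    tab <- table(eg[!is.na(eg)])
    gc[names(tab)] <- as.integer(tab)
    # the first run can itself sit in a group entry (degenerate starts);
    # flank anchoring makes this impossible in practice, but count it
    first_eg <- kaut$entry_group[runs$state[1]]
    if (!is.na(first_eg)) gc[as.character(first_eg)] <-
        gc[as.character(first_eg)] + 1L
  }
  oc <- integer(max(kaut$n_optionals, 0L))
  if (kaut$n_optionals > 0L) {
    names(oc) <- as.character(seq_len(kaut$n_optionals) - 1L)
    eo <- kaut$entry_optional[dest]
    tab <- table(eo[!is.na(eo)])
    oc[names(tab)] <- as.integer(tab)
  }
  # report in forward-strand group ids when aligned to a reverse automaton
  gmap <- attr(kaut, "group_map")
  if (!is.null(gmap) && length(gc) > 0L) {
    out <- gc
    names(out) <- as.character(gmap)
    gc <- out[order(as.integer(names(out)))]
  }
  omap <- attr(kaut, "optional_map")
  if (!is.null(omap) && length(oc) > 0L) {
    out <- oc
    names(out) <- as.character(omap)
    oc <- out[order(as.integer(names(out)))]
  }
  list(length = as.integer(len), group_counts = gc, optional_counts = oc)
}

#' Welch's unequal-variances t statistic for two equal-size windows
#'
#' `t = (mean(S1) - mean(S2)) / sqrt((var(S1) + var(S2)) / p)` with the
#' population variance convention (divide by `p`).  With zero pooled
#' variance the statistic is 0 for equal means and +/-Inf otherwise.
#'
#' @param s1,s2 numeric vectors of equal length `p >= 2`
#' @return the t value
#' @export
welch_t <- function(s1, s2) {
  p <- length(s1)
  if (length(s2) != p || p < 2L) stop("windows must have equal length >= 2")
  m1 <- mean(s1); m2 <- mean(s2)
  v1 <- mean((s1 - m1)^2)
  v2 <- mean((s2 - m2)^2)
  denom <- sqrt((v1 + v2) / p)
  if (denom == 0) {
    if (m1 == m2) return(0)
    return(sign(m1 - m2) * Inf)
  }
  (m1 - m2) / denom
}

# |t| profile over all sliding subwindows of length 2p within s
welch_profile <- function(s, p) {
  w <- length(s)
  n_sub <- w - 2L * p + 1L
  vapply(seq_len(n_sub),
         function(u) welch_t(s[u:(u + p - 1L)], s[(u + p):(u + 2L * p - 1L)]),
         0)
}

# strict local optima of |t| at or above the threshold; ties go to the
# earlier index because later equal values fail the strict comparison
pick_peaks <- function(tvals, threshold) {
  a <- abs(tvals)
  n <- length(a)
  if (n == 0L) return(integer(0))
  left <- c(-Inf, a[-n])
  right <- c(a[-1], -Inf)
  which(a >= threshold & a > left & a > right)
}

#' Detect signal windows containing short consecutive events
#'
#' Splits the first-pass alignment into non-overlapping windows of
#' `m_events` events each, scans every window with a sliding Welch's t of
#' half-window `p` (`w - 2p + 1` subwindows for a window of `w` points),
#' and counts the local-optimum peaks of `|t|` at or above `t_threshold`
#' as apparent context changes.  Windows with more context changes than
#' `m_events` presumably lost short events to the dwell floor and are
#' flagged so that the second pass lowers their minimum dwell by one.
#'
#' @param alignment first-pass `warp_alignment`
#' @param m_events events per window
#' @param p Welch half-window, in signal points
#' @param t_threshold minimum `|t|` for a peak to count as extreme
#' @param s_default the default minimum dwell the override will decrement
#' @return data.frame with one row per window: `start`, `end`,
#'   `n_events`, `n_peaks`, `override`, `s`
#' @export
detect_short_event_windows <- function(alignment, m_events = 6L, p = 3L,
                                       t_threshold = 3.0, s_default = 4L) {
  runs <- path_runs(alignment)
  sig <- alignment$signal
  n_ev <- nrow(runs)
  win_of_event <- ceiling(seq_len(n_ev) / m_events)
  out <- lapply(unique(win_of_event), function(wid) {
    ev <- which(win_of_event == wid)
    a <- runs$start[ev[1]]
    b <- runs$end[ev[length(ev)]]
    w <- b - a + 1L
    if (w < 2L * p) {
      return(data.frame(start = a, end = b, n_events = length(ev),
                        n_peaks = NA_integer_, override = FALSE))
    }
    tv <- welch_profile(sig[a:b], p)
    npk <- length(pick_peaks(tv, t_threshold))
    data.frame(start = a, end = b, n_events = length(ev),
               n_peaks = npk, override = npk > m_events)
  })
  out <- do.call(rbind, out)
  out$s <- ifelse(out$override, pmax(1L, s_default - 1L), s_default)
  out
}

#' Configuration for the per-read two-pass caller
#'
#' Defaults follow the method's standard operating point: 6-mer contexts,
#' minimum event size `s = 4`, adaptive windows of `m_events = 6` events
#' scanned with a Welch half-window of `p = 3` points and peak threshold
#' 3.0, and the polishing filters of [fit_polish_spline()].
#'
#' @param s default minimum dwell (signal points per state)
#' @param m_events events per adaptive-restriction window
#' @param p Welch half-window (signal points)
#' @param t_threshold extremeness threshold on `|t|`
#' @param spline_max_dev,spline_sigma_mult,spline_min_pairs polishing
#'   filters, see [fit_polish_spline()]
#' @param min_segment minimum segment length accepted by normalization
#' @return list of class `warp_read_config`
#' @export
warp_read_config <- function(s = 4L, m_events = 6L, p = 3L,
                             t_threshold = 3.0, spline_max_dev = 2.0,
                             spline_sigma_mult = 1.5, spline_min_pairs = 8L,
                             min_segment = 20L) {
  structure(
    list(s = as.integer(s), m_events = as.integer(m_events),
         p = as.integer(p), t_threshold = t_threshold,
         spline_max_dev = spline_max_dev,
         spline_sigma_mult = spline_sigma_mult,
         spline_min_pairs = as.integer(spline_min_pairs),
         min_segment = as.integer(min_segment)),
    class = "warp_read_config"
  )
}

#' Two-pass per-read STR length estimation
#'
#' The full per-read procedure: median-normalize the extracted segment,
#' align with the default dwell floor, aggregate per-state signal values
#' and fit the polishing spline, polish the signal, flag short-event
#' windows, re-align with the adaptive dwell policy, and read the final
#' length off the second warping path.
#'
#' @param segment raw signal slice spanning left flank + STR + right flank
#' @param kaut the strand-appropriate `kmer_automaton`
#' @param config a `warp_read_config`
#' @return list with `pass1` and `final` count results (see
#'   [count_str_length()]), both alignments, the spline, the window table,
#'   and the normalized/polished signals
#' @export
run_two_pass <- function(segment, kaut, config = warp_read_config()) {
  norm <- normalize_median(segment, min_len = config$min_segment)
  a1 <- align_signal(norm, kaut, dwell_policy(config$s))
  c1 <- count_str_length(a1, kaut)
  agg <- aggregate_state_signals(a1, kaut)
  spl <- withCallingHandlers(
    fit_polish_spline(agg, max_dev = config$spline_max_dev,
                      sigma_mult = config$spline_sigma_mult,
                      min_pairs = config$spline_min_pairs),
    warning = function(w) invokeRestart("muffleWarning")
  )
  polished <- apply_polish(norm, spl)
  win <- detect_short_event_windows(a1, m_events = config$m_events,
                                    p = config$p,
                                    t_threshold = config$t_threshold,
                                    s_default = config$s)
  ov <- win[win$override, c("start", "end", "s"), drop = FALSE]
  policy2 <- dwell_policy(config$s, overrides = if (nrow(ov)) ov else NULL)
  a2 <- align_signal(polished, kaut, policy2)
  c2 <- count_str_length(a2, kaut)
  list(
    pass1 = c1, final = c2,
    pass1_length = c1$length, final_length = c2$length,
    cost1 = a1$cost, cost2 = a2$cost,
    alignment1 = a1, alignment2 = a2,
    spline = spl, windows = win,
    normalized = norm, polished = polished
  )
}
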
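# Signal preparation: flank localization in the basecall, extraction of
# the STR-spanning raw-signal segment, median normalization, and the
# spline-based polishing transform.

#' Construct a per-read record
#'
#' The neutral per-read container consumed by the whole pipeline: raw
#' signal, basecalled sequence, the base-to-signal index map (for each
#' called base, the first signal index of its event — the interim "move"
#' output of the basecaller), and the mapped strand.
#'
#' @param read_id character scalar
#' @param signal numeric vector of raw current values (instrument units)
#' @param basecall character scalar (A/C/G/T)
#' @param move_index integer vector, same length as the basecall,
#'   nondecreasing, 1-based first signal index of each base's event
#' @param strand `"+"` or `"-"`
#' @param truth optional list of simulator ground-truth annotations
#' @return an object of class `read_record`
#' @export
read_record <- function(read_id, signal, basecall, move_index,
                        strand = c("+", "-"), truth = NULL) {
  strand <- match.arg(strand)
  basecall <- toupper(basecall)
  nb <- nchar(basecall)
  move_index <- as.integer(move_index)
  if (length(move_index) != nb) {
    stop("base-to-signal map length (", length(move_index),
         ") != basecall length (", nb, ")")
  }
  if (is.unsorted(move_index)) {
    stop("base-to-signal map must be nondecreasing")
  }
  if (nb > 0L && (move_index[1] < 1L || move_index[nb] > length(signal))) {
    stop("base-to-signal map indices out of signal range")
  }
  structure(
    list(read_id = as.character(read_id), signal = as.numeric(signal),
         basecall = basecall, move_index = move_index, strand = strand,
         truth = truth),
    class = "read_record"
  )
}

#' @export
print.read_record <- function(x, ...) {
  cat("<read_record> ", x$read_id, " (", x$strand, "): ",
      length(x$signal), " signal points, ", nchar(x$basecall),
      " called bases\n", sep = "")
  invisible(x)
}

#' Locate the flanking sequences in a basecalled read
#'
#' Local alignment (match +1, mismatch -1, gap -1 by default) of each flank
#' against the basecall, on the read's called strand orientation.  Both
#' flanks must score at least `min_score_frac` times their length and the
#' left match must end before the right match starts; otherwise the read is
#' rejected with a `flank_not_found` condition.
#'
#' @param read a `read_record`
#' @param left_flank,right_flank flank sequences as they appear in the
#'   basecall orientation
#' @param min_score_frac acceptance threshold as a fraction of flank length
#' @param match,mismatch,gap local-alignment scoring parameters
#' @return list with 1-based inclusive basecall intervals `left`, `right`
#'   and their alignment `scores`
#' @export
locate_flanks <- function(read, left_flank, right_flank,
                          min_score_frac = 0.7,
                          match = 1, mismatch = -1, gap = 1) {
  stopifnot(inherits(read, "read_record"))
  if (nchar(read$basecall) == 0L) {
    stop(warp_reject("empty basecall", "flank_not_found"))
  }
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE
  )
  hit <- function(flank) {
    al <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(toupper(flank)),
      subject = Biostrings::DNAString(read$basecall),
      type = "local", substitutionMatrix = submat,
      gapOpening = 0, gapExtension = gap
    )
    list(start = Biostrings::start(Biostrings::subject(al)),
         end = Biostrings::end(Biostrings::subject(al)),
         score = Biostrings::score(al))
  }
  lh <- hit(left_flank)
  rh <- hit(right_flank)
  if (lh$score < min_score_frac * nchar(left_flank) ||
      rh$score < min_score_frac * nchar(right_flank)) {
    stop(warp_reject("flank alignment score below threshold",
                     "flank_not_found"))
  }
  if (lh$end >= rh$start) {
    stop(warp_reject("flank matches out of order", "flank_not_found"))
  }
  list(left = c(start = lh$start, end = lh$end),
       right = c(start = rh$start, end = rh$end),
       scores = c(left = lh$score, right = rh$score))
}

#' Extract the raw-signal slice under a basecall interval
#'
#' Uses the base-to-signal map: the slice spans from the first signal index
#' of the interval's first base up to (but excluding) the first signal
#' index of the base after the interval.
#'
#' @param read a `read_record`
#' @param interval integer vector `c(start, end)`, 1-based inclusive base
#'   coordinates
#' @return numeric signal slice with attribute `signal_range`
#' @export
extract_signal_segment <- function(read, interval) {
  stopifnot(inherits(read, "read_record"), length(interval) == 2L)
  b1 <- as.integer(interval[1])
  b2 <- as.integer(interval[2])
  nb <- nchar(read$basecall)
  if (b1 < 1L || b2 > nb || b1 > b2) stop("interval outside basecall range")
  s1 <- read$move_index[b1]
  s2 <- if (b2 < nb) read$move_index[b2 + 1L] - 1L else length(read$signal)
  if (s2 < s1) {
    stop(warp_reject("empty signal slice under basecall interval",
                     "empty_segment"))
  }
  out <- read$signal[s1:s2]
  attr(out, "signal_range") <- c(start = s1, end = s2)
  out
}

#' Median-normalize a raw signal
#'
#' Computes `shift` as the midpoint of the 46.5th and 53.5th percentiles
#' (linear interpolation between order statistics) and `scale` as the
#' median absolute deviation from that shift, then returns
#' `s_i = (r_i - shift) / scale`; the normalized values have median
#' absolute value 1.
#'
#' @param r numeric raw signal
#' @param min_len minimum number of points required
#' @return an object of class `normalized_signal` with fields `values`,
#'   `shift`, `scale`
#' @export
normalize_median <- function(r, min_len = 20L) {
  r <- as.numeric(r)
  if (length(r) < min_len) {
    stop(warp_reject(paste0("signal shorter than ", min_len, " points"),
                     "degenerate_signal"))
  }
  shift <- mean(quantile(r, c(0.465, 0.535), names = FALSE, type = 7))
  scale <- median(abs(r - shift))
  if (scale == 0) {
    stop(warp_reject("constant signal: normalization scale is zero",
                     "degenerate_signal"))
  }
  structure(list(values = (r - shift) / scale, shift = shift, scale = scale),
            class = "normalized_signal")
}

#' @export
print.normalized_signal <- function(x, ...) {
  cat("<normalized_signal> ", length(x$values), " points; shift = ",
      signif(x$shift, 6), ", scale = ", signif(x$scale, 6), "\n", sep = "")
  invisible(x)
}

# population standard deviation (divide by n)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Aggregate aligned signal values per automaton state
#'
#' Pools all signal points aligned to each state across the whole warping
#' path (states visited several times pool all their visits) and reports
#' the observed mean `m`, population standard deviation `sigma`, point
#' count, and the state's expected level `e`.
#'
#' @param alignment a `warp_alignment`
#' @param kaut the `kmer_automaton` the alignment was computed against
#' @return data.frame with one row per visited state
#' @export
aggregate_state_signals <- function(alignment, kaut) {
  stopifnot(inherits(alignment, "warp_alignment"))
  sig <- alignment$signal
  st <- alignment$path_states
  idx <- split(seq_along(sig), st)
  state_ids <- as.integer(names(idx))
  m <- vapply(idx, function(i) mean(sig[i]), 0)
  sigma <- vapply(idx, function(i) pop_sd(sig[i]), 0)
  count <- lengths(idx)
  data.frame(
    state = state_ids,
    kmer = kaut$states$kmer[state_ids],
    m = unname(m),
    sigma = unname(sigma),
    count = unname(count),
    e = kaut$states$level[state_ids],
    row.names = NULL
  )
}

#' Fit the polishing spline
#'
#' Estimates the non-linear recalibration `f` mapping observed per-state
#' signal means to their expected levels.  Control pairs `(m_j, e_j)` are
#' first filtered: pairs with `|m_j - e_j| > max_dev` or with
#' `sigma_j > sigma_mult * median(sigma)` most likely contain misaligned
#' points and are dropped.  The retained pairs are fitted with a cubic
#' smoothing spline (smoothness chosen by generalized cross-validation),
#' falling back to linear interpolation when the spline cannot be fitted;
#' outside the retained range `f` extrapolates linearly with the boundary
#' slope.  With fewer than `min_pairs` retained pairs, polishing is skipped
#' (identity transform) with a warning.
#'
#' @param agg data.frame from [aggregate_state_signals()] (columns `m`,
#'   `e`, `sigma`)
#' @param max_dev drop pairs with `|m - e|` above this (normalized units)
#' @param sigma_mult drop pairs with `sigma` above `sigma_mult` times the
#'   median sigma
#' @param min_pairs minimum retained pairs required to fit
#' @return an object of class `polish_spline`
#' @export
fit_polish_spline <- function(agg, max_dev = 2.0, sigma_mult = 1.5,
                              min_pairs = 8L) {
  keep <- abs(agg$m - agg$e) <= max_dev &
    agg$sigma <= sigma_mult * median(agg$sigma)
  retained <- agg[keep, , drop = FALSE]
  dropped <- agg[!keep, , drop = FALSE]
  if (nrow(retained) < min_pairs) {
    warning("only ", nrow(retained), " control pairs retained (< ",
            min_pairs, "); polishing skipped, identity transform used")
    return(structure(
      list(identity = TRUE, retained = retained, dropped = dropped),
      class = "polish_spline"
    ))
  }
  # collapse duplicate abscissae, weight by pooled point count
  x <- retained$m
  y <- retained$e
  w <- retained$count
  if (is.null(w)) w <- rep(1, length(x))
  ux <- sort(unique(x))
  if (length(ux) < length(x)) {
    grp <- match(x, ux)
    y <- vapply(seq_along(ux),
                function(i) sum((y * w)[grp == i]) / sum(w[grp == i]), 0)
    w <- vapply(seq_along(ux), function(i) sum(w[grp == i]), 0)
    x <- ux
  } else {
    ord <- order(x)
    x <- x[ord]; y <- y[ord]; w <- w[ord]
  }

  fit <- NULL
  if (length(x) >= 10L) {
    fit <- tryCatch(
      smooth.spline(x, y, w = w, cv = FALSE, keep.data = FALSE),
      error = function(e) NULL
    )
  }
  if (is.null(fit)) {
    # too few points for a smoothing spline: piecewise-linear interpolant
    grid_x <- x
    grid_y <- y
  } else {
    grid_x <- seq(min(x), max(x), length.out = 200L)
    grid_y <- predict(fit, grid_x)$y
  }
  nl <- length(grid_x)
  slope_left <- (grid_y[2] - grid_y[1]) / (grid_x[2] - grid_x[1])
  slope_right <- (grid_y[nl] - grid_y[nl - 1]) / (grid_x[nl] - grid_x[nl - 1])
  structure(
    list(identity = FALSE, grid_x = grid_x, grid_y = grid_y,
         slope_left = slope_left, slope_right = slope_right,
         retained = retained, dropped = dropped),
    class = "polish_spline"
  )
}

#' Evaluate a polishing spline
#' @param object a `polish_spline`
#' @param x numeric values on the normalized-signal scale
#' @param ... ignored
#' @return `f(x)`
#' @export
predict.polish_spline <- function(object, x, ...) {
  if (isTRUE(object$identity)) return(x)
  gx <- object$grid_x
  gy <- object$grid_y
  out <- approx(gx, gy, xout = x, rule = 1)$y
  lo <- x < gx[1]
  hi <- x > gx[length(gx)]
  out[lo] <- gy[1] + object$slope_left * (x[lo] - gx[1])
  out[hi] <- gy[length(gy)] + object$slope_right * (x[hi] - gx[length(gx)])
  out
}

#' @export
print.polish_spline <- function(x, ...) {
  if (isTRUE(x$identity)) {
    cat("<polish_spline> identity (too few control pairs)\n")
  } else {
    cat("<polish_spline> ", nrow(x$retained), " control pairs retained, ",
        nrow(x$dropped), " dropped; range [",
        signif(x$grid_x[1], 4), ", ",
        signif(x$grid_x[length(x$grid_x)], 4), "]\n", sep = "")
  }
  invisible(x)
}

#' Apply a polishing spline to a normalized signal
#'
#' Pointwise application of `f`; the signal length is unchanged.
#'
#' @param signal a `normalized_signal`
#' @param spline a `polish_spline`
#' @return a `normalized_signal` with polished values
#' @export
apply_polish <- function(signal, spline) {
  stopifnot(inherits(signal, "normalized_signal"),
            inherits(spline, "polish_spline"))
  signal$values <- predict(spline, signal$values)
  signal$polished <- TRUE
  signal
}

#' Baseline STR length from the basecalled sequence alone
#'
#' The simple basecall-space estimate: locate both flanks by local
#' alignment and report the number of called bases strictly between the
#' left flank's match end and the right flank's match start.  Reads whose
#' flanks fail the score or ordering checks are rejected.
#'
#' @inheritParams locate_flanks
#' @param ... passed on to [locate_flanks()]
#' @return integer length estimate
#' @export
baseline_length_from_basecall <- function(read, left_flank, right_flank, ...) {
  loc <- locate_flanks(read, left_flank, right_flank, ...)
  as.integer(loc$right["start"] - loc$left["end"] - 1L)
}
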
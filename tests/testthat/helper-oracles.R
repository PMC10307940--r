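# Independent oracles used by the test suite.  These deliberately avoid
# the package's own code paths: the language oracle expands expression
# trees by brute force, and the alignment oracle is a run-length dynamic
# program over explicit state paths rather than the per-point dwell
# counter used by the engine.

# All words an expression tree can produce with repeat counts 1..max_rep,
# optional blocks in or out, and IUPAC symbols fully branched.
oracle_expand_words <- function(expr, max_rep = 3L) {
  if (is.character(expr)) expr <- parse_repeat_expression(expr)
  expand_node <- function(node) {
    switch(node$kind,
      literal = {
        opts <- lapply(strsplit(node$seq, "")[[1]], iupac_bases)
        Reduce(function(acc, o) as.vector(outer(acc, o, paste0)),
               opts, accumulate = FALSE, init = "")
      },
      optional = unique(c("", expand_nodes(node$nodes))),
      "repeat" = {
        once <- expand_nodes(node$nodes)
        out <- once
        words <- once
        if (max_rep > 1L) {
          for (i in seq_len(max_rep - 1L)) {
            words <- as.vector(outer(words, once, paste0))
            out <- c(out, words)
          }
        }
        unique(out)
      }
    )
  }
  expand_nodes <- function(nodes) {
    Reduce(function(acc, node) {
      unique(as.vector(outer(acc, expand_node(node), paste0)))
    }, nodes, init = "")
  }
  unique(expand_nodes(expr$nodes))
}

# Minimal-cost dwell-feasible alignment by a run-length recursion over
# explicit state paths (successor sets from the automaton's transition
# table), memoized on (start index, state).
oracle_align_cost <- function(signal, kaut, s) {
  m <- length(signal)
  n <- nrow(kaut$states)
  levels <- kaut$states$level
  succ <- vector("list", n)
  for (r in seq_len(nrow(kaut$trans))) {
    f <- kaut$trans$from[r]
    succ[[f]] <- c(succ[[f]], kaut$trans$to[r])
  }
  is_accept <- rep(FALSE, n)
  is_accept[kaut$accept] <- TRUE
  # prefix sums of |signal - level_j| per state, computed lazily
  memo <- matrix(NA_real_, nrow = m, ncol = n)
  run_cost <- function(i, l, j) sum(abs(signal[i:(i + l - 1L)] - levels[j]))
  rec <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    best <- Inf
    max_l <- m - i + 1L
    if (max_l >= s) {
      acc <- sum(abs(signal[i:(i + s - 1L)] - levels[j]))
      for (l in s:max_l) {
        if (l > s) acc <- acc + abs(signal[i + l - 1L] - levels[j])
        endpos <- i + l
        if (endpos > m) {
          if (is_accept[j]) best <- min(best, acc)
        } else {
          for (k in succ[[j]]) best <- min(best, acc + rec(endpos, k))
        }
      }
    }
    memo[i, j] <<- best
    best
  }
  min(Inf, vapply(kaut$start, function(j) rec(1L, j), 0))
}

# Hand-rolled type-7 percentile (linear interpolation between order
# statistics), independent of stats::quantile.
oracle_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Textbook Welch statistic with the population-variance convention.
oracle_welch <- function(s1, s2) {
  p <- length(s1)
  v1 <- sum((s1 - mean(s1))^2) / p
  v2 <- sum((s2 - mean(s2))^2) / p
  (mean(s1) - mean(s2)) / sqrt((v1 + v2) / p)
}

# Construct a tiny k-mer-automaton-shaped object directly (the alignment
# engine only needs states/levels, transitions, pred sets, start/accept).
toy_automaton <- function(levels, edges, start, accept,
                          roles = NULL, kmers = NULL) {
  n <- length(levels)
  if (is.null(roles)) roles <- rep("repeat", n)
  if (is.null(kmers)) kmers <- sprintf("S%02d", seq_len(n))
  trans <- if (length(edges) > 0L) {
    data.frame(from = vapply(edges, `[`, 0L, 1L),
               to = vapply(edges, `[`, 0L, 2L))
  } else data.frame(from = integer(0), to = integer(0))
  pred <- vector("list", n)
  for (r in seq_len(nrow(trans))) {
    t <- trans$to[r]
    pred[[t]] <- c(pred[[t]], trans$from[r])
  }
  for (i in seq_len(n)) {
    p <- pred[[i]]
    if (is.null(p)) pred[[i]] <- integer(0)
    else pred[[i]] <- p[order(kmers[p], p)]
  }
  structure(
    list(
      states = data.frame(id = seq_len(n), kmer = kmers,
                          base_state = seq_len(n), level = levels,
                          role = roles, group = NA_integer_),
      trans = trans, pred = pred,
      start = as.integer(start), accept = as.integer(accept),
      entry_group = rep(NA_integer_, n),
      entry_optional = rep(NA_integer_, n),
      k = 1L, n_groups = 0L, n_optionals = 0L
    ),
    class = "kmer_automaton"
  )
}

# Random toy automaton for the oracle-equivalence grid: a chain with
# optional extra skip/backward edges, random levels.
random_toy_automaton <- function(n_states, extra_edges = 1L) {
  levels <- round(runif(n_states, -2, 2), 3)
  edges <- lapply(seq_len(n_states - 1L), function(i) c(i, i + 1L))
  for (e in seq_len(extra_edges)) {
    from <- sample(n_states, 1L)
    to <- sample(n_states, 1L)
    if (from != to) edges[[length(edges) + 1L]] <- c(from, to)
  }
  toy_automaton(levels, unique(edges), start = 1L, accept = n_states)
}

# Independent lower median (lower of the two central order statistics).
oracle_lower_median <- function(x) sort(x)[floor((length(x) + 1) / 2)]
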
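# Squiggle simulator: synthetic pore models, raw reads with known truth,
# and diploid locus datasets.  Gives every other module a download-free
# test surface; it emulates dwell-time variation, level noise, per-read
# shift/scale and optional non-linear level distortion, but not
# basecaller errors beyond uniform substitutions or event-skip artifacts.

#' Simulation configuration
#'
#' Defaults reflect the standard operating conditions the caller is built
#' for: contexts are read on average 8.5 times (shifted negative-binomial
#' dwell), and the level noise defaults to a quarter of the synthetic pore
#' model's guaranteed minimum level separation.
#'
#' @param k k-mer context length of the synthetic pore model
#' @param dwell_mean mean signal points per k-mer context (>= 1)
#' @param dwell_size dispersion of the shifted negative-binomial dwell law
#'   (1 = shifted geometric; the default 6 thins 1-2 point events to the
#'   few percent seen in real squiggles)
#' @param noise_sd Gaussian level noise SD, in pore-model (normalized)
#'   units; `NULL` picks 0.25 x the model's guaranteed minimum level gap
#' @param scale_range,shift_range per-read raw-signal scale and shift are
#'   drawn uniformly from these ranges (instrument units)
#' @param distortion optional monotone function applied to the ideal
#'   signal values before the raw-scale transform, emulating non-linear
#'   miscalibration that median normalization cannot remove
#' @param flank_length flank length emitted around the STR region
#' @param reads_per_allele reads simulated per allele
#' @param basecall_error uniform substitution rate applied to the emitted
#'   basecall (signal untouched)
#' @return list of class `sim_config`
#' @export
sim_config <- function(k = 3L, dwell_mean = 8.5, dwell_size = 6,
                       noise_sd = NULL,
                       scale_range = c(8, 12), shift_range = c(70, 90),
                       distortion = NULL, flank_length = 110L,
                       reads_per_allele = 10L, basecall_error = 0) {
  stopifnot(dwell_mean >= 1, is.null(noise_sd) || noise_sd >= 0)
  structure(
    list(k = as.integer(k), dwell_mean = dwell_mean,
         dwell_size = dwell_size, noise_sd = noise_sd,
         scale_range = scale_range, shift_range = shift_range,
         distortion = distortion, flank_length = as.integer(flank_length),
         reads_per_allele = as.integer(reads_per_allele),
         basecall_error = basecall_error),
    class = "sim_config"
  )
}

#' Generate a synthetic pore model
#'
#' Expected levels are a seeded random permutation of an equally spaced
#' grid spanning `[-span, span]`, so any two distinct k-mers are separated
#' by at least `2 * span / (4^k - 1)` (the value [pore_model_min_gap()]
#' reports).  A symmetric span of 2 makes the median absolute level 1,
#' matching the scale that median normalization produces, so simulated
#' reads land near the model scale after normalization.
#'
#' @param k context length (2 to 6)
#' @param seed RNG seed (restored afterwards); deterministic tables under
#'   a fixed seed
#' @param span half-width of the level grid
#' @return a `pore_model`
#' @export
make_synthetic_pore_model <- function(k, seed = 1L, span = 2) {
  stopifnot(k >= 2L, k <= 6L)
  kmers <- all_kmers(k)
  grid <- seq(-span, span, length.out = length(kmers))
  levels <- with_local_seed(seed, sample(grid))
  names(levels) <- kmers
  pore_model(levels)
}

# shifted negative-binomial dwell: minimum 1 point, mean `dwell_mean`.
# `size` controls dispersion: size = 1 is the maximally dispersed shifted
# geometric; larger sizes thin the left tail the way real translocation
# dwell times do (very few 1-2 point events at an 8-9 point mean).
draw_dwells <- function(n, dwell_mean, size = 6) {
  if (dwell_mean <= 1) return(rep(1L, n))
  if (size == 1) return(1L + rgeom(n, prob = 1 / dwell_mean))
  1L + stats::rnbinom(n, size = size, mu = dwell_mean - 1)
}

apply_substitutions <- function(sequence, rate) {
  if (rate <= 0) return(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, "")
  }
  paste(chars, collapse = "")
}

#' Simulate one raw nanopore read for a known sequence
#'
#' Decomposes the sequence into overlapping k-mers, emits a
#' shifted-geometric number of signal points per context at the expected
#' level plus Gaussian noise, optionally distorts the values, and applies
#' a per-read raw shift/scale.  The exact base-to-signal map and all
#' generated quantities are recorded as truth, never re-derived.
#'
#' @param sequence the sequence the pore reads, 5' to 3' in signal order
#'   (pass the reverse complement for a reverse-strand read)
#' @param model a `pore_model`
#' @param config a `sim_config`
#' @param read_id identifier for the read
#' @param strand reported mapping strand of the read
#' @return a `read_record` whose `truth` field holds the dwells, the
#'   per-k-mer event starts, and the generation parameters
#' @export
simulate_read <- function(sequence, model, config = sim_config(),
                          read_id = "sim_read", strand = "+") {
  sequence <- toupper(sequence)
  k <- model$k
  nb <- nchar(sequence)
  stopifnot(nb >= k)
  noise_sd <- config$noise_sd
  if (is.null(noise_sd)) {
    noise_sd <- 0.25 * pore_model_min_gap(model)
  }
  n_kmers <- nb - k + 1L
  kmers <- substring(sequence, seq_len(n_kmers), seq_len(n_kmers) + k - 1L)
  levels <- unname(model$levels[kmers])
  if (anyNA(levels)) stop("sequence contains k-mers missing from the model")
  dwells <- draw_dwells(n_kmers, config$dwell_mean, config$dwell_size)
  total <- sum(dwells)
  ideal <- rep(levels, dwells) + rnorm(total, 0, noise_sd)
  if (!is.null(config$distortion)) ideal <- config$distortion(ideal)
  scale <- runif(1, config$scale_range[1], config$scale_range[2])
  shift <- runif(1, config$shift_range[1], config$shift_range[2])
  raw <- ideal * scale + shift
  event_start <- cumsum(dwells) - dwells + 1L
  # base b is the most recent base of k-mer b - k + 1; leading bases share
  # the first event
  move_index <- event_start[pmax(1L, seq_len(nb) - k + 1L)]
  basecall <- apply_substitutions(sequence, config$basecall_error)
  read_record(
    read_id = read_id, signal = raw, basecall = basecall,
    move_index = move_index, strand = strand,
    truth = list(sequence = sequence, dwells = dwells,
                 event_start = event_start, scale = scale, shift = shift,
                 noise_sd = noise_sd)
  )
}

#' Simulate a diploid STR locus dataset with known truth
#'
#' Instantiates the repeat expression at the two requested repeat counts,
#' wraps the alleles in seeded random flanks, and simulates reads split
#' between the alleles and across both strands.  Basecalls are the exact
#' instantiated sequences unless `config$basecall_error` adds substitution
#' noise.
#'
#' @param expression repeat expression string or `repeat_expression`
#' @param alleles integer vector of 2 repeat counts (group-0 counts for a
#'   single-group expression), or a list of 2 count vectors for
#'   multi-group expressions
#' @param model a `pore_model` (its `k` must match `config$k`)
#' @param config a `sim_config`
#' @param seed RNG seed governing flanks, dwell, noise and strand layout
#' @return list with `reads`, `truth` (sorted allele lengths in bases and
#'   zygosity), `left_flank`, `right_flank`, `expression`,
#'   `allele_sequences`
#' @export
simulate_locus_dataset <- function(expression, alleles, model,
                                   config = sim_config(), seed = 1L) {
  if (is.character(expression)) expression <- parse_repeat_expression(expression)
  if (!is.list(alleles)) alleles <- list(alleles[1], alleles[2])
  stopifnot(length(alleles) == 2L)
  with_local_seed(seed, {
    flank <- function() paste(sample(c("A", "C", "G", "T"),
                                     config$flank_length, replace = TRUE),
                              collapse = "")
    left <- flank()
    right <- flank()
    strs <- vapply(alleles, function(cc)
      instantiate_expression(expression, group_counts = cc), "")
    lens <- nchar(strs)
    reads <- list()
    for (a in 1:2) {
      full <- paste0(left, strs[a], right)
      for (r in seq_len(config$reads_per_allele)) {
        strand <- if (r %% 2L == 1L) "+" else "-"
        seq_read <- if (strand == "+") full else revcomp_iupac(full)
        rid <- sprintf("allele%d_read%02d", a, r)
        rec <- simulate_read(seq_read, model, config, read_id = rid,
                             strand = strand)
        rec$truth$allele <- a
        rec$truth$str_length <- lens[a]
        reads[[length(reads) + 1L]] <- rec
      }
    }
    truth_alleles <- sort(lens)
    list(
      reads = reads,
      truth = list(alleles = truth_alleles,
                   zygosity = if (truth_alleles[1] == truth_alleles[2])
                     "homozygous" else "heterozygous"),
      left_flank = left, right_flank = right,
      expression = expression, allele_sequences = strs
    )
  })
}

#' Write a read record to the canonical per-read JSON container
#'
#' One JSON file per read: `read_id`, `strand`, `signal`, `basecall`,
#' `move_index` (and `truth` when present).  This plain-text container is
#' the core input format; FAST5/POD5/BAM adapters are deliberately out of
#' scope.
#'
#' @param read a `read_record`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_read_record <- function(read, path) {
  stopifnot(inherits(read, "read_record"))
  jsonlite::write_json(
    list(read_id = read$read_id, strand = read$strand,
         signal = read$signal, basecall = read$basecall,
         move_index = read$move_index, truth = read$truth),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a read record from the canonical per-read JSON container
#' @param path JSON file written by [write_read_record()]
#' @return a `read_record`
#' @export
read_read_record <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  read_record(
    read_id = x$read_id, signal = x$signal, basecall = x$basecall,
    move_index = x$move_index, strand = x$strand,
    truth = if (!is.null(x$truth)) as.list(x$truth) else NULL
  )
}
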
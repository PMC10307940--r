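# Per-locus orchestration: automaton construction, per-read two-pass
# length estimation, genotyping, and tabular reporting.

#' Pipeline run configuration
#'
#' Bundles every knob of the per-locus pipeline.  Values with a canonical
#' operating point default to it (110-base flanks, 6-mer contexts, dwell
#' floor 4, adaptive windows of 6 events, 2-SD outlier filter, 20%
#' homozygosity fraction, Bayesian-GMM weight prior 0.25 with 5
#' initializations and 1000 iterations); the remaining knobs (Welch
#' half-window, peak threshold, flank-alignment scoring, spline filters)
#' are surfaced here and echoed into every report for reproducibility.
#'
#' @param flank_length flank length used for locating reads and anchoring
#'   the automaton (longer reference flanks are trimmed to this)
#' @param k k-mer context length (must match the pore model)
#' @param s default minimum dwell
#' @param m_events,p,t_threshold adaptive-restriction parameters, see
#'   [detect_short_event_windows()]
#' @param spline_max_dev,spline_sigma_mult,spline_min_pairs polishing
#'   filters, see [fit_polish_spline()]
#' @param flank_min_score_frac,flank_match,flank_mismatch,flank_gap flank
#'   localization scoring, see [locate_flanks()]
#' @param genotype a `genotype_config`
#' @param seed seed recorded in reports and passed to the genotyper
#' @return list of class `warp_config`
#' @export
warp_config <- function(flank_length = 110L, k = 6L, s = 4L,
                        m_events = 6L, p = 3L, t_threshold = 3.0,
                        spline_max_dev = 2.0, spline_sigma_mult = 1.5,
                        spline_min_pairs = 8L,
                        flank_min_score_frac = 0.7, flank_match = 1,
                        flank_mismatch = -1, flank_gap = 1,
                        genotype = genotype_config(seed = seed), seed = 1L) {
  structure(
    list(flank_length = as.integer(flank_length), k = as.integer(k),
         s = as.integer(s), m_events = as.integer(m_events),
         p = as.integer(p), t_threshold = t_threshold,
         spline_max_dev = spline_max_dev,
         spline_sigma_mult = spline_sigma_mult,
         spline_min_pairs = as.integer(spline_min_pairs),
         flank_min_score_frac = flank_min_score_frac,
         flank_match = flank_match, flank_mismatch = flank_mismatch,
         flank_gap = flank_gap, genotype = genotype, seed = seed),
    class = "warp_config"
  )
}

read_config_of <- function(config) {
  warp_read_config(
    s = config$s, m_events = config$m_events, p = config$p,
    t_threshold = config$t_threshold,
    spline_max_dev = config$spline_max_dev,
    spline_sigma_mult = config$spline_sigma_mult,
    spline_min_pairs = config$spline_min_pairs
  )
}

# trim reference flanks to the configured anchoring length: keep the side
# adjacent to the STR region
trim_flanks <- function(left_flank, right_flank, flank_length) {
  nl <- nchar(left_flank)
  list(
    left = substr(left_flank, max(1L, nl - flank_length + 1L), nl),
    right = substr(right_flank, 1L, min(nchar(right_flank), flank_length))
  )
}

#' Definition of one STR locus
#'
#' @param name locus identifier
#' @param expression repeat expression string, or `NULL` to auto-generate
#'   from `region` and `motif`
#' @param left_flank,right_flank reference flanking sequences (forward
#'   strand)
#' @param region reference sequence of the STR region (used with `motif`
#'   when no expression is given)
#' @param motif repeat unit for auto-generation
#' @param chrom,start,end optional genomic coordinates (0-based half-open)
#' @return list of class `str_locus`
#' @export
str_locus <- function(name, expression = NULL, left_flank, right_flank,
                      region = NULL, motif = NULL, chrom = NA, start = NA,
                      end = NA) {
  if (is.null(expression)) {
    if (is.null(region) || is.null(motif)) {
      stop("either 'expression' or both 'region' and 'motif' are required")
    }
    expression <- autogenerate_expression(region, motif)
  }
  structure(
    list(name = name, expression = expression, left_flank = left_flank,
         right_flank = right_flank, chrom = chrom, start = start, end = end),
    class = "str_locus"
  )
}

#' Genotype one STR locus from a set of reads
#'
#' Builds the forward and reverse k-mer automata for the locus, runs the
#' two-pass per-read estimator on every read, tallies discards (flank
#' failures, infeasible alignments, degenerate segments) without ever
#' aborting the locus, and genotypes the surviving per-read lengths.
#'
#' @param locus an `str_locus`
#' @param reads list of `read_record`s overlapping the locus
#' @param model a `pore_model`
#' @param config a `warp_config`
#' @return list of class `locus_report`: `per_read` data.frame, `call`,
#'   `discards` named counts, the locus and the config echo
#' @export
call_locus <- function(locus, reads, model, config = warp_config(k = model$k)) {
  stopifnot(inherits(locus, "str_locus"), inherits(model, "pore_model"))
  if (config$k != model$k) stop("config k does not match the pore model")
  fl <- trim_flanks(locus$left_flank, locus$right_flank, config$flank_length)
  expr <- parse_repeat_expression(locus$expression)
  base_fwd <- build_base_automaton(expr, fl$left, fl$right, k = model$k)
  kaut_fwd <- expand_to_kmer_automaton(base_fwd, model)
  kaut_rev <- reverse_strand_automaton(expr, fl$left, fl$right, model)
  rc <- read_config_of(config)

  rows <- list()
  discards <- c(flank_not_found = 0L, alignment_infeasible = 0L,
                degenerate_signal = 0L, empty_segment = 0L, other = 0L)
  lengths <- integer(0)
  for (read in reads) {
    res <- tryCatch({
      if (read$strand == "+") {
        lf <- fl$left; rf <- fl$right; kaut <- kaut_fwd
      } else {
        lf <- revcomp_iupac(fl$right); rf <- revcomp_iupac(fl$left)
        kaut <- kaut_rev
      }
      loc <- locate_flanks(read, lf, rf,
                           min_score_frac = config$flank_min_score_frac,
                           match = config$flank_match,
                           mismatch = config$flank_mismatch,
                           gap = config$flank_gap)
      segment <- extract_signal_segment(
        read, c(loc$left["start"], loc$right["end"])
      )
      run_two_pass(segment, kaut, rc)
    }, warp_reject = function(e) e)
    if (is_warp_reject(res)) {
      key <- intersect(class(res), names(discards))
      key <- if (length(key) > 0L) key[1] else "other"
      discards[key] <- discards[key] + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = read$read_id, strand = read$strand, status = key,
        pass1_length = NA_integer_, final_length = NA_integer_,
        cost = NA_real_, group_counts = NA_character_,
        stringsAsFactors = FALSE
      )
    } else {
      lengths <- c(lengths, res$final_length)
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = read$read_id, strand = read$strand, status = "ok",
        pass1_length = res$pass1_length, final_length = res$final_length,
        cost = res$cost2,
        group_counts = as.character(jsonlite::toJSON(
          as.list(res$final$group_counts), auto_unbox = TRUE
        )),
        stringsAsFactors = FALSE
      )
    }
  }
  per_read <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(read_id = character(0), strand = character(0),
               status = character(0), pass1_length = integer(0),
               final_length = integer(0), cost = numeric(0),
               group_counts = character(0))
  call <- genotype_call(lengths, config$genotype)
  structure(
    list(locus = locus, per_read = per_read, call = call,
         discards = discards, n_reads = length(reads),
         n_genotyped = length(lengths), config = config),
    class = "locus_report"
  )
}

#' @export
print.locus_report <- function(x, ...) {
  cat("<locus_report> ", x$locus$name, ": ", x$n_genotyped, "/", x$n_reads,
      " reads genotyped (", sum(x$discards), " discarded)\n", sep = "")
  print(x$call)
  invisible(x)
}

#' Run the pipeline over several loci
#'
#' @param loci list of `str_locus` objects
#' @param reads_by_locus named list (by locus name) of read lists
#' @param model a `pore_model`
#' @param config a `warp_config`
#' @param out_dir optional directory for TSV/JSON reports (created if
#'   needed)
#' @return named list of `locus_report`s
#' @export
run_pipeline <- function(loci, reads_by_locus, model,
                         config = warp_config(k = model$k),
                         out_dir = NULL) {
  reports <- lapply(loci, function(locus) {
    reads <- reads_by_locus[[locus$name]]
    if (is.null(reads)) reads <- list()
    call_locus(locus, reads, model, config)
  })
  names(reports) <- vapply(loci, function(l) l$name, "")
  if (!is.null(out_dir)) write_reports(reports, out_dir)
  reports
}

#' Write per-locus and per-read reports
#'
#' Emits `per_read.tsv` (one row per read with pass-1 and final lengths),
#' `loci.tsv` (one VCF-like row per locus: zygosity, alleles, read
#' counts), and `report.json` with cluster detail and the full
#' configuration echo.
#'
#' @param reports named list of `locus_report`s from [run_pipeline()]
#' @param out_dir output directory
#' @return `out_dir`, invisibly
#' @export
write_reports <- function(reports, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  per_read <- do.call(rbind, lapply(names(reports), function(nm) {
    df <- reports[[nm]]$per_read
    if (nrow(df) > 0L) cbind(locus = nm, df) else NULL
  }))
  if (!is.null(per_read)) {
    write.table(per_read, file.path(out_dir, "per_read.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  loci <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    al <- r$call$alleles
    data.frame(
      locus = nm, chrom = r$locus$chrom, start = r$locus$start,
      end = r$locus$end, zygosity = r$call$zygosity,
      allele1 = if (length(al) >= 1L) al[1] else NA_integer_,
      allele2 = if (length(al) >= 2L) al[2] else
        if (length(al) == 1L) al[1] else NA_integer_,
      n_reads = r$n_reads, n_genotyped = r$n_genotyped,
      n_discarded = sum(r$discards),
      stringsAsFactors = FALSE
    )
  }))
  write.table(loci, file.path(out_dir, "loci.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  detail <- lapply(reports, function(r) {
    list(
      locus = r$locus$name, zygosity = r$call$zygosity,
      alleles = r$call$alleles,
      cluster_sizes = r$call$cluster_sizes,
      retained = r$call$retained, filtered = r$call$filtered,
      discards = as.list(r$discards),
      config = unclass_config(r$config)
    )
  })
  jsonlite::write_json(detail, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

unclass_config <- function(config) {
  out <- unclass(config)
  out$genotype <- unclass(out$genotype)
  out
}
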
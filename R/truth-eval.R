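# Gold-standard derivation from benchmark VCF-style records and the
# evaluation metrics (per-read MAE / MedAE and the genotype distance D).

parse_gt <- function(gt) {
  parts <- strsplit(as.character(gt), "[/|]")[[1]]
  parts <- parts[parts != "."]
  if (length(parts) == 0L) stop("missing genotype field")
  idx <- suppressWarnings(as.integer(parts))
  if (anyNA(idx)) stop("unparseable genotype field: '", gt, "'")
  if (length(idx) == 1L) idx <- c(idx, idx)  # haploid records count twice
  if (length(idx) != 2L) stop("only diploid genotypes are supported: '",
                              gt, "'")
  idx
}

#' Derive diploid allele lengths from variant records over a locus
#'
#' Starting from the reference allele length, adds the length of
#' insertions and subtracts the length of deletions per haplotype.  Each
#' record needs `ref` and `alt` sequences and a genotype `gt`
#' (`"0/1"`-style); the two genotype fields are treated as the two
#' haplotypes in the order given, so a heterozygous single-alt variant
#' contributes its length change to one haplotype only.  Multi-allelic
#' records ( `alt` comma-separated, genotypes like `"1/2"`) are supported.
#'
#' @param ref_length reference allele length of the locus in bases
#' @param records data.frame with columns `ref`, `alt`, `gt` and
#'   optionally `pos`; zero rows mean no variation
#' @return sorted numeric vector `c(m1, m2)` of the two allele lengths
#' @examples
#' derive_allele_lengths(40, data.frame(
#'   ref = c("A", "ATT"), alt = c("ATTTT", "A"), gt = c("0/1", "1/1")))
#' @export
derive_allele_lengths <- function(ref_length, records) {
  stopifnot(is.numeric(ref_length), ref_length >= 0)
  if (is.null(records) || nrow(records) == 0L) {
    return(c(ref_length, ref_length))
  }
  stopifnot(all(c("ref", "alt", "gt") %in% names(records)))
  if ("pos" %in% names(records) && nrow(records) > 1L) {
    # overlapping records are inconsistent: discard the locus
    start <- as.numeric(records$pos)
    end <- start + nchar(as.character(records$ref)) - 1
    ord <- order(start)
    if (any(start[ord][-1] <= end[ord][-nrow(records)])) {
      stop(warp_reject("overlapping variant records over the locus",
                       "inconsistent_records"))
    }
  }
  deltas <- c(0, 0)
  for (i in seq_len(nrow(records))) {
    ref <- toupper(as.character(records$ref[i]))
    alts <- strsplit(toupper(as.character(records$alt[i])), ",")[[1]]
    gt <- parse_gt(records$gt[i])
    if (any(gt > length(alts))) {
      stop(warp_reject("genotype refers to a missing alternative allele",
                       "inconsistent_records"))
    }
    for (h in 1:2) {
      a <- gt[h]
      if (a > 0L) deltas[h] <- deltas[h] + nchar(alts[a]) - nchar(ref)
    }
  }
  sort(ref_length + deltas)
}

#' Combine per-caller allele-length estimates into a consensus truth
#'
#' A locus estimate is accepted when two callers agree exactly, or when at
#' least `k - 1` of `k >= 3` callers report the same allele pair; a single
#' caller, two disagreeing callers, no qualifying majority, or no records
#' at all discard the locus.
#'
#' @param estimates list of length-2 numeric vectors (one per caller with
#'   an estimation; `NULL` entries are dropped)
#' @return an object of class `truth_call`: either an accepted call with
#'   `alleles`, `zygosity` and the supporting caller count, or a discard
#'   with a `reason`
#' @export
consensus_truth <- function(estimates) {
  estimates <- Filter(Negate(is.null), estimates)
  keys <- vapply(estimates,
                 function(e) paste(sort(as.numeric(e)), collapse = ","), "")
  k <- length(keys)
  discard <- function(reason) {
    structure(list(accepted = FALSE, reason = reason, n_callers = k),
              class = "truth_call")
  }
  accept <- function(key, support) {
    alleles <- as.numeric(strsplit(key, ",")[[1]])
    structure(
      list(accepted = TRUE, alleles = alleles,
           zygosity = if (alleles[1] == alleles[2]) "homozygous"
                      else "heterozygous",
           support = support, n_callers = k),
      class = "truth_call"
    )
  }
  if (k == 0L) return(discard("no caller estimations"))
  if (k == 1L) return(discard("only one caller estimation"))
  tab <- sort(table(keys), decreasing = TRUE)
  if (k == 2L) {
    if (length(tab) == 1L) return(accept(names(tab)[1], 2L))
    return(discard("two callers disagree"))
  }
  if (tab[1] >= k - 1L) return(accept(names(tab)[1], as.integer(tab[1])))
  discard("no k-1 caller majority")
}

#' @export
print.truth_call <- function(x, ...) {
  if (isTRUE(x$accepted)) {
    cat("<truth_call> ", x$zygosity, "; alleles ",
        paste(x$alleles, collapse = " / "), " (", x$support, "/",
        x$n_callers, " callers)\n", sep = "")
  } else {
    cat("<truth_call> discarded: ", x$reason, "\n", sep = "")
  }
  invisible(x)
}

#' Per-read error metrics against a truth genotype
#'
#' Each read's error is its minimum absolute distance to either truth
#' allele; MAE is the mean and MedAE the median of these errors.
#'
#' @param calls numeric vector of per-read length estimates
#' @param truth numeric vector of 1 or 2 truth allele lengths
#' @return list with `MAE`, `MedAE` and the per-read `errors`
#' @export
locus_errors <- function(calls, truth) {
  stopifnot(length(calls) >= 1L, length(truth) %in% 1:2)
  if (length(truth) == 1L) truth <- rep(truth, 2)
  errors <- pmin(abs(calls - truth[1]), abs(calls - truth[2]))
  list(MAE = mean(errors), MedAE = median(errors), errors = errors)
}

#' Genotype distance D between a predicted and a true genotype
#'
#' With both genotypes sorted ascending, `D = |y1 - m1| + |y2 - m2|` when
#' either side is heterozygous (a homozygous side contributes its single
#' allele twice) and `D = |y1 - m1|` when both are homozygous.
#'
#' @param predicted numeric vector of 1 (homozygous) or 2 allele lengths
#' @param truth numeric vector of 1 or 2 allele lengths
#' @return the distance D
#' @export
genotype_distance <- function(predicted, truth) {
  stopifnot(length(predicted) %in% 1:2, length(truth) %in% 1:2)
  p_hom <- length(predicted) == 1L || predicted[1] == predicted[2]
  t_hom <- length(truth) == 1L || truth[1] == truth[2]
  if (p_hom && t_hom) {
    return(abs(predicted[1] - truth[1]))
  }
  p <- sort(rep_len(predicted, 2))
  t <- sort(rep_len(truth, 2))
  sum(abs(p - t))
}

#' Locus suitability filter for simple-repeat benchmarking
#'
#' The documented selection rule for loci comparable across tools: a
#' single repeat unit of 2-6 bases (no homopolymers), a reference region
#' longer than 30 bases, and no homopolymer run longer than 6 within it.
#'
#' @param motif the repeat unit
#' @param region_seq reference sequence of the STR region
#' @return logical scalar with attribute `reasons` listing any failures
#' @export
str_locus_filter <- function(motif, region_seq) {
  reasons <- character(0)
  if (nchar(motif) < 2L || nchar(motif) > 6L) {
    reasons <- c(reasons, "repeat unit not 2-6 bases")
  }
  if (nchar(region_seq) <= 30L) {
    reasons <- c(reasons, "reference region not longer than 30 bases")
  }
  runs <- rle(strsplit(toupper(region_seq), "", fixed = TRUE)[[1]])
  if (max(runs$lengths) > 6L) {
    reasons <- c(reasons, "homopolymer run longer than 6")
  }
  out <- length(reasons) == 0L
  attr(out, "reasons") <- reasons
  out
}

#' Read per-caller variant records for a locus from a benchmark VCF
#'
#' Accepts multi-sample VCFs where each sample column carries one caller's
#' genotypes.  Returns, per caller, the records overlapping the locus in
#' the shape [derive_allele_lengths()] consumes.  Requires the `vcfR`
#' package.
#'
#' @param path VCF file (uncompressed or bgzipped)
#' @param chrom,start,end locus interval, 0-based half-open
#' @return named list (one entry per sample) of data.frames with columns
#'   `pos`, `ref`, `alt`, `gt`; samples without a genotyped record over
#'   the locus get `NULL`
#' @export
vcf_locus_records <- function(path, chrom, start, end) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF files requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  pos <- as.numeric(fix[, "POS"])
  refs <- fix[, "REF"]
  sel <- fix[, "CHROM"] == chrom &
    pos + nchar(refs) - 1 > start & pos <= end  # 1-based record vs 0-based locus
  gts <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gts)
  out <- lapply(samples, function(s) {
    g <- gts[sel, s]
    has <- !is.na(g) & g != "." & g != "./." & g != ".|."
    if (!any(has)) return(NULL)
    data.frame(pos = pos[sel][has], ref = refs[sel][has],
               alt = fix[sel, "ALT"][has], gt = g[has],
               stringsAsFactors = FALSE)
  })
  names(out) <- samples
  out
}
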
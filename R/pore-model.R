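# k-mer pore models: lookup tables of expected current levels.

all_kmers <- function(k) {
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  c(rep(list(bases), k), KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE))
  # first position varies slowest so the table is in dictionary order
  sort(do.call(paste0, grid))
}

#' Construct a pore model object
#'
#' @param levels named numeric vector, one entry per k-mer over A/C/G/T
#' @param stdv optional named numeric vector of per-k-mer spreads
#' @return an object of class `pore_model`
#' @export
pore_model <- function(levels, stdv = NULL) {
  if (is.null(names(levels))) stop("'levels' must be a named vector")
  k <- unique(nchar(names(levels)))
  if (length(k) != 1L) stop("inconsistent k-mer lengths in pore model")
  if (any(grepl("[^ACGT]", names(levels)))) {
    stop("pore model k-mers must be over A/C/G/T only")
  }
  missing <- setdiff(all_kmers(k), names(levels))
  if (length(missing) > 0L) {
    stop("pore model incomplete: ", length(missing), " of ", 4^k,
         " k-mers missing (e.g. ", missing[1], ")")
  }
  if (anyDuplicated(names(levels))) stop("duplicated k-mers in pore model")
  structure(list(k = as.integer(k), levels = levels, stdv = stdv),
            class = "pore_model")
}

#' @export
print.pore_model <- function(x, ...) {
  cat("<pore_model> k = ", x$k, "; ", length(x$levels), " k-mers; level range [",
      round(min(x$levels), 3), ", ", round(max(x$levels), 3), "]\n", sep = "")
  invisible(x)
}

#' Load a pore model from an ONT-style tab-separated table
#'
#' Expects a header line and at least two columns: the k-mer and its mean
#' level (`kmer` and `level_mean` if named, otherwise the first two
#' columns).  The table must contain all 4^k k-mers; `k` is inferred from
#' the first record.  Lookups are strand-explicit: no reverse-complement
#' folding is applied.
#'
#' @param path file path
#' @return a `pore_model`
#' @export
load_pore_model <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0L) stop("empty pore model file: ", path)
  kcol <- if ("kmer" %in% names(tab)) "kmer" else names(tab)[1]
  lcol <- if ("level_mean" %in% names(tab)) "level_mean" else names(tab)[2]
  kmers <- toupper(as.character(tab[[kcol]]))
  if (length(unique(nchar(kmers))) != 1L) {
    stop("inconsistent k-mer lengths in pore model file: ", path)
  }
  levels <- as.numeric(tab[[lcol]])
  names(levels) <- kmers
  stdv <- NULL
  if ("level_stdv" %in% names(tab)) {
    stdv <- as.numeric(tab[["level_stdv"]])
    names(stdv) <- kmers
  }
  pore_model(levels, stdv)
}

#' Write a pore model to an ONT-style tab-separated table
#' @param model a `pore_model`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_pore_model <- function(model, path) {
  stopifnot(inherits(model, "pore_model"))
  tab <- data.frame(kmer = names(model$levels),
                    level_mean = unname(model$levels))
  if (!is.null(model$stdv)) tab$level_stdv <- unname(model$stdv)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Minimum pairwise gap between expected levels
#'
#' @param model a `pore_model`
#' @param kmers optional character vector restricting the computation, e.g.
#'   the k-mers of one automaton's states
#' @return smallest absolute difference between two distinct levels
#' @export
pore_model_min_gap <- function(model, kmers = NULL) {
  lv <- model$levels
  if (!is.null(kmers)) lv <- lv[unique(kmers)]
  lv <- sort(unname(lv))
  if (length(lv) < 2L) return(Inf)
  min(diff(lv))
}
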
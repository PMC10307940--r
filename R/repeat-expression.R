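# Repeat regular expressions: the locus description grammar.
#
# Supported syntax: IUPAC nucleotide symbols, skippable blocks in `{}`,
# and repeat groups in `()` that must be traversed at least once.  This is
# the full grammar needed for the complex medically relevant loci (e.g. a
# CAGG repeat with CAGA/CAGC interruptions written as `(CAGG{CAGM})`);
# alternation and bounded counts are deliberately not supported.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

IUPAC_ALPHABET <- names(IUPAC_SETS)

#' Expand one IUPAC symbol to its concrete nucleotides
#' @param symbol single IUPAC character
#' @return character vector of concrete bases (subset of A, C, G, T)
#' @export
iupac_bases <- function(symbol) {
  set <- IUPAC_SETS[[symbol]]
  if (is.null(set)) stop("not an IUPAC symbol: '", symbol, "'")
  set
}

#' Reverse-complement a sequence of IUPAC symbols
#'
#' @param x character scalar over the IUPAC alphabet
#' @return reverse complement, ambiguity codes mapped to their complements
#'   (e.g. M to K)
#' @export
revcomp_iupac <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  comp <- IUPAC_COMPLEMENT[chars]
  if (anyNA(comp)) {
    stop("non-IUPAC character in sequence: '",
         paste(chars[is.na(comp)], collapse = "', '"), "'")
  }
  paste(rev(comp), collapse = "")
}

#' Parse a repeat regular expression
#'
#' Parses the locus grammar into a tree of literal blocks, optional
#' (skippable) blocks written `{...}`, and repeat groups written `(...)`
#' which match one or more traversals of their body.  Repeat groups are
#' assigned dense ids 0, 1, ... left to right; optional blocks get their
#' own dense ids.
#'
#' @param expr character scalar, e.g. `"(CAGG{CAGM})"`
#' @return an object of class `repeat_expression`
#' @examples
#' parse_repeat_expression("(AGC)AACAGCCGCCAC(CGC)")
#' @export
parse_repeat_expression <- function(expr) {
  if (!is.character(expr) || length(expr) != 1L || is.na(expr)) {
    stop("'expr' must be a single character string")
  }
  src <- gsub("[[:space:]]", "", toupper(expr))
  if (nchar(src) == 0L) stop("empty repeat expression")
  chars <- strsplit(src, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% c(IUPAC_ALPHABET, "(", ")", "{", "}")))
  if (length(bad) > 0L) {
    stop("invalid character '", chars[bad[1]], "' at position ", bad[1],
         " of repeat expression")
  }

  pos <- 1L
  n <- length(chars)

  parse_seq <- function(closing) {
    nodes <- list()
    lit <- character(0)
    flush_lit <- function() {
      if (length(lit) > 0L) {
        nodes[[length(nodes) + 1L]] <<- list(
          kind = "literal", seq = paste(lit, collapse = "")
        )
        lit <<- character(0)
      }
    }
    while (pos <= n) {
      ch <- chars[pos]
      if (ch %in% IUPAC_ALPHABET) {
        lit[length(lit) + 1L] <- ch
        pos <<- pos + 1L
      } else if (ch == "(" || ch == "{") {
        flush_lit()
        open_pos <- pos
        pos <<- pos + 1L
        close_ch <- if (ch == "(") ")" else "}"
        sub <- parse_seq(close_ch)
        if (pos > n || chars[pos] != close_ch) {
          stop("unbalanced '", ch, "' opened at position ", open_pos)
        }
        pos <<- pos + 1L
        if (length(sub) == 0L) {
          stop("empty group opened at position ", open_pos)
        }
        nodes[[length(nodes) + 1L]] <- if (ch == "(") {
          list(kind = "repeat", nodes = sub, group = NA_integer_)
        } else {
          list(kind = "optional", nodes = sub, optid = NA_integer_)
        }
      } else {
        # closing bracket
        if (!identical(ch, closing)) {
          stop("unbalanced '", ch, "' at position ", pos)
        }
        break
      }
    }
    flush_lit()
    nodes
  }

  nodes <- parse_seq(closing = NA_character_)
  if (pos <= n) {
    stop("unbalanced '", chars[pos], "' at position ", pos)
  }

  # assign dense ids left-to-right in traversal order
  group_counter <- 0L
  opt_counter <- 0L
  assign_ids <- function(node) {
    if (node$kind == "repeat") {
      node$group <- group_counter
      group_counter <<- group_counter + 1L
      node$nodes <- lapply(node$nodes, assign_ids)
    } else if (node$kind == "optional") {
      node$optid <- opt_counter
      opt_counter <<- opt_counter + 1L
      node$nodes <- lapply(node$nodes, assign_ids)
    }
    node
  }
  nodes <- lapply(nodes, assign_ids)

  structure(
    list(nodes = nodes, n_groups = group_counter, n_optionals = opt_counter,
         source = src),
    class = "repeat_expression"
  )
}

#' Serialize a parsed repeat expression back to its string form
#' @param x a `repeat_expression`
#' @param ... ignored
#' @return character scalar
#' @export
format.repeat_expression <- function(x, ...) {
  fmt <- function(node) {
    switch(node$kind,
      literal = node$seq,
      "repeat" = paste0("(", paste(vapply(node$nodes, fmt, ""), collapse = ""), ")"),
      optional = paste0("{", paste(vapply(node$nodes, fmt, ""), collapse = ""), "}")
    )
  }
  paste(vapply(x$nodes, fmt, ""), collapse = "")
}

#' @export
print.repeat_expression <- function(x, ...) {
  cat("<repeat_expression> ", format(x), "  (", x$n_groups, " repeat group",
      if (x$n_groups != 1) "s", ", ", x$n_optionals, " optional block",
      if (x$n_optionals != 1) "s", ")\n", sep = "")
  invisible(x)
}

#' Reverse-complement a repeat expression
#'
#' Builds the expression describing the reverse strand: node order is
#' reversed recursively and every literal is reverse-complemented (IUPAC
#' codes map to their complements).  Repeat-group ids are re-assigned
#' densely in the new left-to-right order; the attribute `group_map` gives,
#' for each new group id (1-based index), the original forward group id, so
#' per-group repeat counts obtained on the reverse strand can be reported
#' in forward coordinates.
#'
#' @param expr a `repeat_expression`
#' @return a `repeat_expression` with attribute `group_map`
#' @export
reverse_expression <- function(expr) {
  stopifnot(inherits(expr, "repeat_expression"))
  rev_node <- function(node) {
    switch(node$kind,
      literal = list(kind = "literal", seq = revcomp_iupac(node$seq)),
      "repeat" = list(kind = "repeat", nodes = rev_nodes(node$nodes),
                    group = node$group),
      optional = list(kind = "optional", nodes = rev_nodes(node$nodes),
                      optid = node$optid)
    )
  }
  rev_nodes <- function(nodes) lapply(rev(nodes), rev_node)
  reversed <- rev_nodes(expr$nodes)

  # re-assign dense ids, remembering provenance
  group_map <- integer(0)
  opt_map <- integer(0)
  reassign <- function(node) {
    if (node$kind == "repeat") {
      group_map[length(group_map) + 1L] <<- node$group
      node$group <- length(group_map) - 1L
      node$nodes <- lapply(node$nodes, reassign)
    } else if (node$kind == "optional") {
      opt_map[length(opt_map) + 1L] <<- node$optid
      node$optid <- length(opt_map) - 1L
      node$nodes <- lapply(node$nodes, reassign)
    }
    node
  }
  reversed <- lapply(reversed, reassign)
  out <- structure(
    list(nodes = reversed, n_groups = expr$n_groups,
         n_optionals = expr$n_optionals, source = NULL),
    class = "repeat_expression"
  )
  out$source <- format(out)
  attr(out, "group_map") <- group_map
  attr(out, "optional_map") <- opt_map
  out
}

#' Auto-generate a repeat expression from a reference STR region
#'
#' Scans the reference repeat region left to right; every maximal run of
#' exact copies of `motif` becomes a repeat group `(motif)`, and everything
#' between runs (incomplete copies, interruptions) is kept verbatim as a
#' literal block.  Instantiating the result with the observed run lengths
#' reproduces the region exactly.
#'
#' @param region reference sequence of the STR region (A/C/G/T text)
#' @param motif the repeat unit, length >= 1
#' @return character scalar, e.g. `"GGG(AGAGGG)"`
#' @examples
#' autogenerate_expression(paste0("GGG", strrep("AGAGGG", 6)), "AGAGGG")
#' @export
autogenerate_expression <- function(region, motif) {
  region <- toupper(region)
  motif <- toupper(motif)
  if (nchar(motif) < 1L) stop("'motif' must have length >= 1")
  if (nchar(region) < 1L) stop("'region' must be non-empty")
  L <- nchar(motif)
  n <- nchar(region)
  if (!grepl(motif, region, fixed = TRUE)) {
    warning("motif '", motif, "' not found in region; returning the region ",
            "as a single literal block")
    return(region)
  }
  out <- character(0)
  lit <- character(0)
  i <- 1L
  while (i <= n) {
    if (i + L - 1L <= n && substr(region, i, i + L - 1L) == motif) {
      if (length(lit) > 0L) {
        out[length(out) + 1L] <- paste(lit, collapse = "")
        lit <- character(0)
      }
      while (i + L - 1L <= n && substr(region, i, i + L - 1L) == motif) {
        i <- i + L
      }
      out[length(out) + 1L] <- paste0("(", motif, ")")
    } else {
      lit[length(lit) + 1L] <- substr(region, i, i)
      i <- i + 1L
    }
  }
  if (length(lit) > 0L) out[length(out) + 1L] <- paste(lit, collapse = "")
  paste(out, collapse = "")
}

#' Instantiate a repeat expression into a concrete sequence
#'
#' Expands each repeat group the requested number of times.  Optional
#' blocks are skipped unless selected via `optionals`; IUPAC ambiguity
#' symbols are instantiated with their first concrete nucleotide
#' (alphabetical order).
#'
#' @param expr a `repeat_expression` or expression string
#' @param group_counts integer vector of traversal counts, one per repeat
#'   group in group-id order (recycled if length 1)
#' @param optionals logical vector, one per optional block id: include the
#'   block on every traversal? Default all `FALSE`.
#' @return character scalar with the instantiated sequence
#' @export
instantiate_expression <- function(expr, group_counts = 1L, optionals = NULL) {
  if (is.character(expr)) expr <- parse_repeat_expression(expr)
  stopifnot(inherits(expr, "repeat_expression"))
  if (expr$n_groups > 0L) {
    group_counts <- rep_len(as.integer(group_counts), expr$n_groups)
    if (any(group_counts < 1L)) stop("repeat groups require counts >= 1")
  }
  if (is.null(optionals)) {
    optionals <- rep(FALSE, max(expr$n_optionals, 1L))
  } else {
    optionals <- rep_len(as.logical(optionals), max(expr$n_optionals, 1L))
  }
  inst <- function(node) {
    switch(node$kind,
      literal = {
        chars <- strsplit(node$seq, "", fixed = TRUE)[[1]]
        paste(vapply(chars, function(ch) iupac_bases(ch)[1], ""), collapse = "")
      },
      optional = {
        if (isTRUE(optionals[node$optid + 1L])) {
          paste(vapply(node$nodes, inst, ""), collapse = "")
        } else ""
      },
      "repeat" = {
        body <- paste(vapply(node$nodes, inst, ""), collapse = "")
        strrep(body, group_counts[node$group + 1L])
      }
    )
  }
  paste(vapply(expr$nodes, inst, ""), collapse = "")
}
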
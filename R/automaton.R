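# Finite-state automata modeling an STR locus.
#
# The base automaton has one state per nucleotide (IUPAC symbols allowed in
# the repeat region), chains for the two flanks, skip edges realizing `{}`
# blocks and back edges realizing `()` repeat groups.  The k-mer automaton
# expands it so that each state is a length-k path (a k-mer context) and
# carries the expected current level looked up in a pore model.

new_base_env <- function() {
  env <- new.env(parent = emptyenv())
  env$base <- character(0)
  env$role <- character(0)
  env$group <- integer(0)
  env$from <- integer(0)
  env$to <- integer(0)
  env$repeat_entries <- list()
  env$optional_entries <- list()
  env
}

add_state <- function(env, base, role, group = NA_integer_) {
  id <- length(env$base) + 1L
  env$base[id] <- base
  env$role[id] <- role
  env$group[id] <- group
  id
}

add_trans <- function(env, from, to) {
  env$from <- c(env$from, from)
  env$to <- c(env$to, to)
}

# Compile a node list into a fragment: entry states, exit states, and
# whether the whole fragment can be skipped.
compile_nodes <- function(env, nodes, role, group = NA_integer_) {
  frag_literal <- function(node) {
    chars <- strsplit(node$seq, "", fixed = TRUE)[[1]]
    ids <- vapply(chars, function(ch) add_state(env, ch, role, group), 0L)
    if (length(ids) > 1L) {
      for (i in seq_len(length(ids) - 1L)) add_trans(env, ids[i], ids[i + 1L])
    }
    list(entries = ids[1], exits = ids[length(ids)], skip = FALSE)
  }
  frag_one <- function(node) {
    switch(node$kind,
      literal = frag_literal(node),
      optional = {
        f <- compile_nodes(env, node$nodes, role, group)
        key <- as.character(node$optid)
        env$optional_entries[[key]] <-
          c(env$optional_entries[[key]], f$entries)
        list(entries = f$entries, exits = f$exits, skip = TRUE)
      },
      "repeat" = {
        f <- compile_nodes(env, node$nodes, role, node$group)
        for (e in f$exits) for (s in f$entries) add_trans(env, e, s)
        key <- as.character(node$group)
        env$repeat_entries[[key]] <- c(env$repeat_entries[[key]], f$entries)
        list(entries = f$entries, exits = f$exits, skip = f$skip)
      }
    )
  }
  frags <- lapply(nodes, frag_one)
  entries <- integer(0)
  exits <- integer(0)
  all_skip <- TRUE
  for (f in frags) {
    # connect everything currently "open at the right" to this fragment
    for (e in exits) for (s in f$entries) add_trans(env, e, s)
    if (all_skip) entries <- c(entries, f$entries)
    exits <- if (f$skip) c(exits, f$exits) else f$exits
    all_skip <- all_skip && f$skip
  }
  list(entries = entries, exits = exits, skip = all_skip)
}

#' Build the base (nucleotide-level) automaton of an STR locus
#'
#' States are single nucleotides tagged with their role (left flank, repeat
#' region, right flank) and owning repeat group; the accepted language is
#' exactly `left_flank . w . right_flank` for every word `w` matching the
#' repeat expression.
#'
#' @param expr a `repeat_expression` or expression string
#' @param left_flank,right_flank concrete flanking sequences (A/C/G/T),
#'   each at least `k` bases long
#' @param k k-mer context length the automaton will later be expanded to
#'   (flanks shorter than `k` leave the start context undefined)
#' @return an object of class `base_automaton`
#' @export
build_base_automaton <- function(expr, left_flank, right_flank, k = 6L) {
  if (is.character(expr)) expr <- parse_repeat_expression(expr)
  stopifnot(inherits(expr, "repeat_expression"))
  left_flank <- toupper(left_flank)
  right_flank <- toupper(right_flank)
  for (fl in c(left_flank, right_flank)) {
    if (nchar(fl) < k) {
      stop("flank shorter than k = ", k, ": start context undefined")
    }
    if (grepl("[^ACGT]", fl)) stop("flanks must contain only A/C/G/T")
  }
  env <- new_base_env()
  lchars <- strsplit(left_flank, "", fixed = TRUE)[[1]]
  lids <- vapply(lchars, function(ch) add_state(env, ch, "left_flank"), 0L)
  for (i in seq_len(length(lids) - 1L)) add_trans(env, lids[i], lids[i + 1L])

  frag <- compile_nodes(env, expr$nodes, role = "repeat")

  rchars <- strsplit(right_flank, "", fixed = TRUE)[[1]]
  rids <- vapply(rchars, function(ch) add_state(env, ch, "right_flank"), 0L)
  for (i in seq_len(length(rids) - 1L)) add_trans(env, rids[i], rids[i + 1L])

  left_exit <- lids[length(lids)]
  for (s in frag$entries) add_trans(env, left_exit, s)
  exits <- frag$exits
  if (frag$skip) exits <- c(exits, left_exit)
  for (e in exits) add_trans(env, e, rids[1])

  trans <- unique(data.frame(from = env$from, to = env$to))
  structure(
    list(
      states = data.frame(id = seq_along(env$base), base = env$base,
                          role = env$role, group = env$group,
                          stringsAsFactors = FALSE),
      trans = trans,
      start = lids[1],
      accept = rids[length(rids)],
      repeat_entries = env$repeat_entries,
      optional_entries = env$optional_entries,
      expr = expr,
      left_flank = left_flank,
      right_flank = right_flank,
      k = as.integer(k)
    ),
    class = "base_automaton"
  )
}

#' @export
print.base_automaton <- function(x, ...) {
  cat("<base_automaton> ", nrow(x$states), " states, ", nrow(x$trans),
      " transitions; expression ", format(x$expr), "\n", sep = "")
  invisible(x)
}

#' Test whether a word is accepted by a base automaton
#'
#' NFA simulation; IUPAC states match any of their concrete nucleotides.
#'
#' @param aut a `base_automaton`
#' @param word character scalar (A/C/G/T)
#' @return logical scalar
#' @export
automaton_accepts <- function(aut, word) {
  chars <- strsplit(toupper(word), "", fixed = TRUE)[[1]]
  if (length(chars) == 0L) return(FALSE)
  matches <- function(id, ch) ch %in% iupac_bases(aut$states$base[id])
  succ <- split(aut$trans$to, aut$trans$from)
  frontier <- if (matches(aut$start, chars[1])) aut$start else integer(0)
  for (ch in chars[-1]) {
    if (length(frontier) == 0L) return(FALSE)
    nxt <- unique(unlist(succ[as.character(frontier)], use.names = FALSE))
    if (is.null(nxt)) return(FALSE)
    frontier <- nxt[vapply(nxt, matches, TRUE, ch = ch)]
  }
  aut$accept %in% frontier
}

#' Shortest word accepted by a base automaton
#'
#' Breadth-first search from the start state; IUPAC states contribute their
#' alphabetically first concrete nucleotide.
#'
#' @param aut a `base_automaton`
#' @return character scalar
#' @export
shortest_accepted_word <- function(aut) {
  succ <- split(aut$trans$to, aut$trans$from)
  n <- nrow(aut$states)
  word <- rep(NA_character_, n)
  word[aut$start] <- iupac_bases(aut$states$base[aut$start])[1]
  queue <- aut$start
  while (length(queue) > 0L) {
    cur <- queue[1]
    queue <- queue[-1]
    if (cur == aut$accept) return(word[cur])
    for (nx in succ[[as.character(cur)]]) {
      if (is.na(word[nx])) {
        word[nx] <- paste0(word[cur], iupac_bases(aut$states$base[nx])[1])
        queue <- c(queue, nx)
      }
    }
  }
  stop("automaton has no accepting path")
}

#' Expand a base automaton into k-mer space
#'
#' Each state of the result is a length-k path of the base automaton,
#' identified by the pair (k-mer string, base-automaton end state): k-mers
#' with identical sequence arising at different structural positions stay
#' distinct so that repeat counting remains positional.  IUPAC symbols are
#' expanded into one state per concrete nucleotide choice, and every state
#' carries the expected current level of its k-mer from the pore model.
#'
#' @param base a `base_automaton`
#' @param model a `pore_model` covering all 4^k k-mers
#' @return an object of class `kmer_automaton`
#' @export
expand_to_kmer_automaton <- function(base, model) {
  stopifnot(inherits(base, "base_automaton"), inherits(model, "pore_model"))
  k <- model$k
  if (nchar(base$left_flank) < k || nchar(base$right_flank) < k) {
    stop("flanks must be at least k = ", k, " bases long")
  }

  env <- new.env(parent = emptyenv())
  env$key2id <- new.env(parent = emptyenv())
  env$kmer <- character(0)
  env$bstate <- integer(0)
  env$from <- integer(0)
  env$to <- integer(0)

  get_id <- function(bstate, kmer) {
    key <- paste0(bstate, "|", kmer)
    id <- env$key2id[[key]]
    if (is.null(id)) {
      id <- length(env$kmer) + 1L
      env$kmer[id] <- kmer
      env$bstate[id] <- bstate
      assign(key, id, envir = env$key2id)
      attr(id, "new") <- TRUE
    }
    id
  }

  # the left flank is a concrete chain at least k long, so the initial
  # context is unique: flank bases 1..k ending in flank state k
  start_kmer <- substr(base$left_flank, 1L, k)
  start_id <- get_id(k, start_kmer)
  succ <- split(base$trans$to, base$trans$from)
  queue <- start_id
  while (length(queue) > 0L) {
    cur <- queue[1]
    queue <- queue[-1]
    cur_b <- env$bstate[cur]
    cur_kmer <- env$kmer[cur]
    for (nb in succ[[as.character(cur_b)]]) {
      for (x in iupac_bases(base$states$base[nb])) {
        nk <- paste0(substr(cur_kmer, 2L, k), x)
        nid <- get_id(nb, nk)
        if (isTRUE(attr(nid, "new"))) queue <- c(queue, nid)
        env$from <- c(env$from, as.integer(cur))
        env$to <- c(env$to, as.integer(nid))
      }
    }
  }

  n <- length(env$kmer)
  levels <- unname(model$levels[env$kmer])
  if (anyNA(levels)) {
    stop("pore model is missing k-mers: ",
         paste(unique(env$kmer[is.na(levels)]), collapse = ", "))
  }
  bs <- env$bstate
  states <- data.frame(
    id = seq_len(n),
    kmer = env$kmer,
    base_state = bs,
    level = levels,
    role = base$states$role[bs],
    group = base$states$group[bs],
    stringsAsFactors = FALSE
  )
  trans <- unique(data.frame(from = env$from, to = env$to))
  trans <- trans[trans$from != trans$to, , drop = FALSE]  # no self loops

  # predecessor sets, each sorted by (k-mer, id) for deterministic
  # tie-breaking in the alignment dynamic program
  pred <- vector("list", n)
  pl <- split(trans$from, trans$to)
  for (key in names(pl)) {
    p <- pl[[key]]
    ord <- order(states$kmer[p], p)
    pred[[as.integer(key)]] <- p[ord]
  }
  for (i in seq_len(n)) if (is.null(pred[[i]])) pred[[i]] <- integer(0)

  entry_group <- rep(NA_integer_, n)
  for (key in names(base$repeat_entries)) {
    ids <- which(bs %in% base$repeat_entries[[key]])
    entry_group[ids] <- as.integer(key)
  }
  entry_optional <- rep(NA_integer_, n)
  for (key in names(base$optional_entries)) {
    ids <- which(bs %in% base$optional_entries[[key]])
    entry_optional[ids] <- as.integer(key)
  }

  accepts <- which(bs == base$accept)
  accepts <- accepts[order(states$kmer[accepts], accepts)]

  structure(
    list(states = states, trans = trans, pred = pred,
         start = as.integer(start_id), accept = as.integer(accepts),
         entry_group = entry_group, entry_optional = entry_optional,
         k = k, n_groups = base$expr$n_groups,
         n_optionals = base$expr$n_optionals),
    class = "kmer_automaton"
  )
}

#' @export
print.kmer_automaton <- function(x, ...) {
  cat("<kmer_automaton> k = ", x$k, "; ", nrow(x$states), " states, ",
      nrow(x$trans), " transitions\n", sep = "")
  invisible(x)
}

#' Build the k-mer automaton for the reverse strand of a locus
#'
#' Equals the forward construction applied to the reverse-complemented,
#' order-reversed expression with the reverse-complemented flanks swapped.
#' A read mapped to the reverse strand is aligned (in native temporal
#' order) against this automaton.  The attribute `group_map` maps reverse
#' group ids back to forward group ids for reporting.
#'
#' @param expr a `repeat_expression` or expression string
#' @param left_flank,right_flank forward-strand flanks
#' @param model a `pore_model`
#' @return a `kmer_automaton` with attribute `group_map`
#' @export
reverse_strand_automaton <- function(expr, left_flank, right_flank, model) {
  if (is.character(expr)) expr <- parse_repeat_expression(expr)
  rex <- reverse_expression(expr)
  base <- build_base_automaton(rex, revcomp_iupac(right_flank),
                               revcomp_iupac(left_flank), k = model$k)
  kaut <- expand_to_kmer_automaton(base, model)
  attr(kaut, "group_map") <- attr(rex, "group_map")
  attr(kaut, "optional_map") <- attr(rex, "optional_map")
  kaut
}
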
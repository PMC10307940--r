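# Repeat-expression grammar, automaton construction, k-mer expansion,
# strand symmetry, and pore-model I/O.

test_that("repeat expressions parse into the expected structure", {
  e <- parse_repeat_expression("(CAGG{CAGM})")
  expect_length(e$nodes, 1L)
  rep_node <- e$nodes[[1]]
  expect_equal(rep_node$kind, "repeat")
  expect_equal(rep_node$group, 0L)
  expect_equal(rep_node$nodes[[1]]$kind, "literal")
  expect_equal(rep_node$nodes[[1]]$seq, "CAGG")
  expect_equal(rep_node$nodes[[2]]$kind, "optional")
  expect_equal(rep_node$nodes[[2]]$nodes[[1]]$seq, "CAGM")

  e2 <- parse_repeat_expression("(AGC)AACAGCCGCCAC(CGC)")
  kinds <- vapply(e2$nodes, `[[`, "", "kind")
  expect_equal(kinds, c("repeat", "literal", "repeat"))
  expect_equal(e2$n_groups, 2L)
  expect_equal(vapply(e2$nodes[c(1, 3)], `[[`, 0L, "group"), c(0L, 1L))

  e3 <- parse_repeat_expression("ACGT")
  expect_equal(vapply(e3$nodes, `[[`, "", "kind"), "literal")
  expect_equal(e3$n_groups, 0L)
})

test_that("parsing round-trips and reports errors with positions", {
  for (src in c("(CAGG{CAGM})", "(AGC)AACAGCCGCCAC(CGC)", "ACGT",
                "GGG(AGAGGG)", "((CAGG)CAGM)(CAGA)(CA)")) {
    expect_equal(format(parse_repeat_expression(src)), src)
  }
  expect_error(parse_repeat_expression("(CAG"), "unbalanced.*position 1")
  expect_error(parse_repeat_expression("CAG)"), "unbalanced.*position 4")
  expect_error(parse_repeat_expression("CA()G"), "empty group.*position 3")
  expect_error(parse_repeat_expression("CAXG"), "invalid character 'X' at position 3")
  expect_error(parse_repeat_expression(""), "empty")
})

test_that("expression auto-generation reproduces the reference region", {
  expect_equal(
    autogenerate_expression(paste0("GGG", strrep("AGAGGG", 6)), "AGAGGG"),
    "GGG(AGAGGG)"
  )
  expect_equal(autogenerate_expression("CAGCAGCAG", "CAG"), "(CAG)")
  expect_equal(autogenerate_expression("CAGCAGCAACAG", "CAG"),
               "(CAG)CAA(CAG)")
  expect_warning(
    out <- autogenerate_expression("AAAA", "CAG"),
    "not found"
  )
  expect_equal(out, "AAAA")

  # re-instantiation property on random regions
  set.seed(101)
  for (i in 1:25) {
    motif <- paste(sample(c("A", "C", "G", "T"), sample(2:4, 1), TRUE),
                   collapse = "")
    parts <- character(0)
    counts <- integer(0)
    for (b in seq_len(sample(1:3, 1))) {
      cnt <- sample(1:5, 1)
      parts <- c(parts,
                 paste(sample(c("A", "C", "G", "T"), sample(1:6, 1), TRUE),
                       collapse = ""),
                 strrep(motif, cnt))
    }
    region <- paste(parts, collapse = "")
    expr_str <- suppressWarnings(autogenerate_expression(region, motif))
    expr <- parse_repeat_expression(expr_str)
    # observed run lengths: count motif copies per group greedily again
    if (expr$n_groups > 0L) {
      # instantiate with every feasible count vector up to the region
      # length and require one of them to reproduce the region
      max_units <- nchar(region) %/% nchar(motif)
      grid <- expand.grid(rep(list(seq_len(max_units)), expr$n_groups))
      hits <- apply(grid, 1, function(cc)
        instantiate_expression(expr, group_counts = cc) == region)
      expect_true(any(hits), info = paste(region, motif, expr_str))
    } else {
      expect_equal(expr_str, region)
    }
  }
})

test_that("base automaton language matches brute-force expansion", {
  flanks <- list(left = "TTTTTT", right = "AAAAAA")
  aut <- build_base_automaton("(CAG)", flanks$left, flanks$right, k = 3)
  expect_equal(shortest_accepted_word(aut), "TTTTTTCAGAAAAAA")
  expect_true(automaton_accepts(aut, "TTTTTTCAGCAGAAAAAA"))
  expect_false(automaton_accepts(aut, "TTTTTTCAAAAAAA"))
  expect_false(automaton_accepts(aut, "TTTTTTAAAAAA"))  # >= 1 traversal

  # optional block: words with and without the interruption are accepted
  aut2 <- build_base_automaton("(CAGG{CAGM})", "TTTTTT", "AAAAAA", k = 3)
  expect_true(automaton_accepts(aut2, "TTTTTTCAGGCAGACAGGAAAAAA"))
  expect_true(automaton_accepts(aut2, "TTTTTTCAGGCAGGAAAAAA"))
  expect_true(automaton_accepts(aut2, "TTTTTTCAGGCAGCAAAAAA"))
  expect_false(automaton_accepts(aut2, "TTTTTTCAGACAGGAAAAAA"))

  # language equivalence on random small expressions, repeat counts <= 3
  set.seed(202)
  exprs <- c("(CAG)", "(AT)GG(CT)", "AC{GT}A", "(CA{GT})", "(AGC)T(GA)")
  for (src in exprs) {
    words <- oracle_expand_words(src, max_rep = 3L)
    aut <- build_base_automaton(src, "TTTT", "GGGG", k = 3)
    for (w in words) {
      expect_true(automaton_accepts(aut, paste0("TTTT", w, "GGGG")),
                  info = paste(src, w))
    }
    # perturbed words must not be accepted unless they are in the language
    for (w in sample(words, min(5, length(words)))) {
      chars <- strsplit(w, "")[[1]]
      if (length(chars) < 2) next
      i <- sample(length(chars), 1)
      chars[i] <- setdiff(c("A", "C", "G", "T"), chars[i])[1]
      w2 <- paste(chars, collapse = "")
      in_lang <- w2 %in% oracle_expand_words(src, max_rep = 4L)
      expect_equal(automaton_accepts(aut, paste0("TTTT", w2, "GGGG")),
                   in_lang, info = paste(src, w2))
    }
  }
})

test_that("k-mer expansion produces overlapping contexts with levels", {
  model2 <- make_synthetic_pore_model(2, seed = 3)
  aut <- build_base_automaton("ACGT", "TTTT", "GGGG", k = 2)
  ka <- expand_to_kmer_automaton(aut, model2)
  # every transition overlaps by k-1
  for (r in seq_len(nrow(ka$trans))) {
    a <- ka$states$kmer[ka$trans$from[r]]
    b <- ka$states$kmer[ka$trans$to[r]]
    expect_equal(substr(a, 2, 2), substr(b, 1, 1))
  }
  # pred sets are exactly the incoming transitions
  for (j in seq_len(nrow(ka$states))) {
    expect_setequal(ka$pred[[j]], ka$trans$from[ka$trans$to == j])
  }
  expect_false(anyNA(ka$states$level))

  model3 <- test_model()
  ka3 <- test_automaton("(CAG)", test_flanks(), model3)
  rep_kmers <- ka3$states$kmer[ka3$states$role == "repeat"]
  expect_true(all(c("AGC", "GCA", "CAG") %in% rep_kmers))
  # cycle: AGC -> GCA -> CAG -> AGC among the positionally merged states
  cyc <- ka3$states[ka3$states$kmer %in% c("AGC", "GCA", "CAG") &
                      ka3$states$role == "repeat", ]
  pure <- cyc$id[!duplicated(cyc$kmer)]
  sub <- ka3$trans[ka3$trans$from %in% cyc$id & ka3$trans$to %in% cyc$id, ]
  expect_gte(nrow(sub), 3L)
})

test_that("IUPAC symbols expand to one state per concrete nucleotide", {
  model3 <- test_model()
  ka <- test_automaton("(CAGM)", test_flanks(), model3)
  # the M position yields both A and C instantiations of its k-mers
  last <- substring(ka$states$kmer, 3, 3)
  m_states <- ka$states[ka$states$role == "repeat" &
                          substring(ka$states$kmer, 1, 2) == "AG", ]
  expect_setequal(unique(substring(m_states$kmer, 3, 3)), c("A", "C"))
})

test_that("accepted words induce valid k-mer state paths and vice versa", {
  model3 <- test_model()
  flanks <- list(left = "TTAT", right = "GGCG")
  base <- build_base_automaton("(CAG)", flanks$left, flanks$right, k = 3)
  ka <- expand_to_kmer_automaton(base, model3)
  succ <- split(ka$trans$to, ka$trans$from)
  for (count in 1:4) {
    w <- paste0(flanks$left, strrep("CAG", count), flanks$right)
    expect_true(automaton_accepts(base, w))
    # walk the k-mer automaton along the word greedily
    frontier <- ka$start
    expect_equal(ka$states$kmer[ka$start], substr(w, 1, 3))
    steps <- 0L
    for (i in 4:nchar(w)) {
      kmer_i <- substr(w, i - 2, i)
      nxt <- unique(unlist(succ[as.character(frontier)], use.names = FALSE))
      frontier <- nxt[ka$states$kmer[nxt] == kmer_i]
      expect_gt(length(frontier), 0)
      steps <- steps + 1L
    }
    expect_true(any(frontier %in% ka$accept))
    # transitions between distinct states == word length - k
    expect_equal(steps, nchar(w) - 3L)
  }
})

test_that("reverse-strand automata mirror the forward construction", {
  e <- parse_repeat_expression("(CAG)")
  r <- reverse_expression(e)
  expect_equal(format(r), "(CTG)")
  expect_equal(revcomp_iupac("CAGM"), "KCTG")
  expect_equal(format(reverse_expression(parse_repeat_expression("(CAGG{CAGM})"))),
               "({KCTG}CCTG)")

  model3 <- test_model()
  flanks <- test_flanks()
  fwd <- test_automaton("(CAG)", flanks, model3)
  rev <- reverse_strand_automaton("(CAG)", flanks$left, flanks$right, model3)
  expect_equal(nrow(rev$states), nrow(fwd$states))
  expect_equal(nrow(rev$trans), nrow(fwd$trans))
  # multi-group: ids map back to forward coordinates
  rev2 <- reverse_strand_automaton("(AGC)T(GA)", flanks$left, flanks$right,
                                   model3)
  expect_equal(attr(rev2, "group_map"), c(1L, 0L))
})

test_that("pore model loading enforces completeness and strandness", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("kmer\tlevel_mean", "AAAAAA\t80.5"), tmp)
  expect_error(load_pore_model(tmp), "incomplete")

  model3 <- test_model()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pore_model(model3, path)
  back <- load_pore_model(path)
  expect_equal(back$k, 3L)
  expect_length(back$levels, 64L)
  expect_equal(back$levels, model3$levels)
  # no implicit strand folding
  expect_false(isTRUE(all.equal(unname(back$levels["ACG"]),
                                unname(back$levels["CGT"]))))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("kmer\tlevel_mean", "AAA\t80.5", "AAAA\t81.5"), bad)
  expect_error(load_pore_model(bad), "inconsistent")
})
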
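# Shared simulation fixtures, built in code at test time.  Small flanks
# and a k = 3 synthetic pore model keep the suite fast while exercising
# the same machinery as the full-size configuration.

test_model <- function(seed = 7L) make_synthetic_pore_model(3L, seed = seed)

test_flanks <- function(seed = 11L, len = 30L) {
  squiggleSTR:::with_local_seed(seed, list(
    left = paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
    right = paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
  ))
}

test_automaton <- function(expr = "(CAG)", flanks = test_flanks(),
                           model = test_model()) {
  base <- build_base_automaton(expr, flanks$left, flanks$right, k = model$k)
  expand_to_kmer_automaton(base, model)
}

# simulate a single read over left + motif^count + right and return the
# read plus its extracted locus-spanning segment
sim_locus_read <- function(count = 10L, expr = "(CAG)",
                           flanks = test_flanks(), model = test_model(),
                           config = sim_config(k = 3L, flank_length = 30L),
                           seed = NULL, read_id = "read") {
  run <- function() {
    str_seq <- instantiate_expression(expr, group_counts = count)
    full <- paste0(flanks$left, str_seq, flanks$right)
    read <- simulate_read(full, model, config, read_id = read_id)
    read$truth$str_length <- nchar(str_seq)
    read
  }
  if (is.null(seed)) run() else squiggleSTR:::with_local_seed(seed, run())
}
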
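# Shared in-code fixtures for the toy walking examples.

# table holding every canonical k-mer of `seqs`, each at a flat count
flat_table <- function(seqs, k = 5L, count = 10L, min_count = 1L) {
  kms <- unique(unlist(lapply(seqs, kmerize, k = k)))
  can <- unique(canonicalize(kms))
  kmer_count_table(stats::setNames(rep(count, length(can)), can),
                   k = k, min_count = min_count)
}

# 13-bp toy whose 5-mer graph has no reverse-strand fold-backs, so toy walks
# are exactly the injected events
TOY <- "CGGCCTTTCCATA"
TOY_SNV <- "CGGCCTATCCATA"        # T>A at position 7
TOY_ITD <- "CGGCCTTTCTTTCCATA"    # tandem duplication of CTTT (pos 5-8)

toy_target <- function(seq = TOY, k = 5L, mode = "reference")
  km_target(seq, k, name = "toy", mode = mode)

default_toy_cfg <- walker_config(count_threshold = 4, ratio_threshold = 0.05)

# full pipeline on a simulated scenario: reads -> count table -> calls
run_scenario_pipeline <- function(name, seed, cfg = walker_config(),
                                  keep_filtered = FALSE) {
  sc <- scenario(name, seed = seed)
  tab <- count_reads(sc$readset$reads, k = sc$k,
                     qualities = sc$readset$qualities, min_count = 2)
  calls <- if (sc$target$mode == "variant")
    interpret_variant_target(sc$target, tab, cfg, keep_filtered = keep_filtered)
  else
    call_target(sc$target, tab, cfg, keep_filtered = keep_filtered)
  list(scenario = sc, table = tab, calls = calls)
}

call_signatures <- function(calls)
  sort(vapply(calls, function(cl)
    paste(cl$call_type, cl$position, cl$removed, cl$added), character(1)))

truth_signatures <- function(truth)
  sort(paste(truth$call_type, truth$position, truth$removed, truth$added))
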
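test_that("trim_to_variant strips common anchors and left-aligns", {
  expect_equal(trim_to_variant("ACGTGCATTAGCC", "ACGTGCGTTAGCC"),
               list(position = 7L, removed = "A", added = "G"))
  expect_equal(trim_to_variant("ACGTGCATTAGCC", "ACGTGCATGCATTAGCC"),
               list(position = 9L, removed = "", added = "GCAT"))
  expect_equal(trim_to_variant("ACGTGCATTAGCC", "ACGTGCATTAGCC"),
               list(position = 0L, removed = "", added = ""))
  # homopolymer ambiguity: the prefix anchor wins, so the insertion is
  # reported at the single placement adjacent to its upstream copy -- every
  # equivalent placement of the extra A yields the identical diff
  tv <- trim_to_variant("CCAAAAGG", "CCAAAAAGG")
  expect_equal(tv$position, 7L)
  expect_equal(tv$added, "A")
  for (p in 3:7) {
    alt <- paste0(substr("CCAAAAGG", 1, p - 1), "A",
                  substr("CCAAAAGG", p, 8))
    expect_equal(trim_to_variant("CCAAAAGG", alt), tv)
  }
})

test_that("insertion subtypes follow the flank-identity rules", {
  # NPM1-style site: insertion point flanked upstream by TCTG
  ref <- "AACCGGTCTGAAAATTTCCC"
  pos <- 11L  # upstream flank ref[7..10] == "TCTG", downstream "AAAA"
  expect_equal(classify_insertion("TCTG", ref, pos), "ITD")        # exact copy
  expect_equal(classify_insertion("CCTG", ref, pos), "I&I")        # 3/4 = 75%
  expect_equal(classify_insertion("CATG", ref, pos), "Insertion")  # 2/4, not > 50%
  # downstream flank can also carry the duplication
  expect_equal(classify_insertion("AAAA", ref, pos), "ITD")
  # too close to the sequence start: only the downstream flank is usable
  expect_equal(classify_insertion("AACC", "AACCGGTTTT", 1L), "ITD")
})

test_that("event classification is a total function over (removed, added)", {
  ref <- "ACGTGCATTAGCC"
  expect_equal(classify_event("", "", ref, 0L), "Reference")
  expect_equal(classify_event("A", "G", ref, 7L), "Substitution")
  expect_equal(classify_event("TG", "GTCCGA", ref, 4L), "Indel")
  expect_equal(classify_event("A", "", ref, 7L), "Deletion")
  expect_equal(classify_event("AT", "GC", ref, 7L), "Substitution")
  # every generated pair maps to exactly one type
  set.seed(5)
  types <- c("Reference", "Substitution", "Deletion", "Insertion", "ITD",
             "I&I", "Indel")
  for (i in 1:50) {
    rm <- if (runif(1) < 0.3) "" else random_dna(sample(1:6, 1))
    ad <- if (runif(1) < 0.3) "" else random_dna(sample(1:6, 1))
    got <- classify_event(rm, ad, ref, 7L)
    expect_length(got, 1L)
    expect_true(got %in% types)
  }
})

test_that("the coverage ratio contrasts branch and replaced-target coverage", {
  tgt <- toy_target()
  mk <- function(ref_count, alt_count) {
    kr <- canonicalize(kmerize(TOY, 5))
    ka <- canonicalize(kmerize(TOY_SNV, 5))
    shared <- intersect(kr, ka)  # anchors carry reads from both haplotypes
    counts <- c(stats::setNames(rep(ref_count, length(setdiff(kr, ka))),
                                setdiff(kr, ka)),
                stats::setNames(rep(alt_count, length(setdiff(ka, kr))),
                                setdiff(ka, kr)),
                stats::setNames(rep(ref_count + alt_count, length(shared)),
                                shared))
    kmer_count_table(counts[counts > 0], k = 5, min_count = 1)
  }
  cfg <- walker_config(count_threshold = 2, ratio_threshold = 0.01)
  het <- mk(10L, 10L)
  w <- explore(tgt, het, cfg)[[1]]
  q <- quantify(w, tgt, het)
  expect_equal(q$ratio, 0.5)
  expect_equal(q$min_coverage, 10L)
  hom <- mk(0L, 10L)
  w2 <- explore(tgt, hom, cfg)[[1]]
  expect_equal(quantify(w2, tgt, hom)$ratio, 1)
  low <- mk(96L, 4L)
  w3 <- explore(tgt, low, cfg)[[1]]
  expect_equal(quantify(w3, tgt, low)$ratio, 0.04)
})

test_that("zero-coverage and ratio filters flag and hide calls by default", {
  tgt <- toy_target()
  # heterozygous duplication, but a downstream target k-mer (TCCAT) is absent
  kms <- unique(canonicalize(c(kmerize(TOY, 5), kmerize(TOY_ITD, 5))))
  counts <- stats::setNames(rep(10L, length(kms)), kms)
  counts <- counts[names(counts) != canonicalize("TCCAT")]
  tab <- kmer_count_table(counts, k = 5, min_count = 1)
  cfg <- walker_config(count_threshold = 4)
  hidden <- call_target(tgt, tab, cfg)
  shown <- call_target(tgt, tab, cfg, keep_filtered = TRUE)
  expect_length(hidden, 0L)
  expect_length(shown, 1L)
  expect_true("zero_coverage_target" %in% shown[[1]]$filters)
  expect_equal(shown[[1]]$call_type, "ITD")

  # a 4% branch at P = 0.01 walks but is flagged below_ratio at P = 0.05
  kms_ref <- canonicalize(kmerize(TOY, 5))
  kms_alt <- setdiff(canonicalize(kmerize(TOY_SNV, 5)), kms_ref)
  counts2 <- c(stats::setNames(rep(96L, length(kms_ref)), kms_ref),
               stats::setNames(rep(4L, length(kms_alt)), kms_alt))
  tab2 <- kmer_count_table(counts2, k = 5, min_count = 1)
  w <- explore(tgt, tab2, walker_config(count_threshold = 2,
                                        ratio_threshold = 0.01))
  call <- kmwalk:::walk_to_call(w[[1]], tgt, tab2)
  flagged <- apply_filters(list(call), tgt, tab2,
                           walker_config(ratio_threshold = 0.05))[[1]]
  clean <- apply_filters(list(call), tgt, tab2,
                         walker_config(ratio_threshold = 0.01))[[1]]
  expect_true("below_ratio" %in% flagged$filters)
  expect_length(clean$filters, 0L)

  # fully covered heterozygous substitution: no flags
  het <- kmer_count_table(
    stats::setNames(rep(10L, length(kms)), kms), k = 5, min_count = 1)
  ok <- call_target(tgt, het, cfg)
  expect_true(all(vapply(ok, function(cl) length(cl$filters) == 0L,
                         logical(1))))
})

test_that("walk selection covers every branch edge with minimal total weight", {
  tgt <- toy_target()
  tab <- flat_table(c(TOY, TOY_SNV, TOY_ITD))
  cfg <- walker_config(count_threshold = 4, ratio_threshold = 0.01)
  walks <- explore(tgt, tab, cfg)
  sel <- select_walks(walks, tgt)
  # both events carry disjoint branch edges: both survive, lighter one first
  expect_length(sel, 2L)
  expect_equal(sel[[1]]$assembled_sequence, TOY_ITD)  # 4 branch edges < 6
  expect_equal(sel[[2]]$assembled_sequence, TOY_SNV)
  # a walk contributing no uncovered branch edge is discarded
  dup <- select_walks(list(walks[[1]], walks[[1]]), tgt)
  expect_length(dup, 1L)
  # single walk: trivially selected
  expect_length(select_walks(walks[1], tgt), 1L)
})

test_that("call_target composes the pipeline end to end on toys", {
  tgt <- toy_target()
  cfg <- walker_config(count_threshold = 4)
  # mutant-only table: homozygous substitution at full ratio
  hom <- flat_table(TOY_SNV)
  calls <- call_target(tgt, hom, cfg)
  expect_length(calls, 1L)
  expect_equal(calls[[1]]$call_type, "Substitution")
  expect_equal(calls[[1]]$position, 7L)
  expect_equal(calls[[1]]$removed, "T")
  expect_equal(calls[[1]]$added, "A")
  expect_equal(calls[[1]]$ratio, 1)
  expect_equal(calls[[1]]$notation, "t/A")
  # heterozygous mixture: ratio 0.5
  het <- flat_table(c(TOY, TOY_SNV))
  calls2 <- call_target(tgt, het, cfg)
  expect_length(calls2, 1L)
  expect_equal(calls2[[1]]$ratio, 0.5)
  # target-only table: a single Reference call
  refcalls <- call_target(tgt, flat_table(TOY), cfg)
  expect_length(refcalls, 1L)
  expect_equal(refcalls[[1]]$call_type, "Reference")
  expect_equal(refcalls[[1]]$ratio, 1)
  # unexpressed target: no calls, informative message
  expect_message(
    none <- call_target(tgt, kmer_count_table(k = 5), cfg),
    "not expressed")
  expect_length(none, 0L)
})

test_that("genomic positions derive from the header offset", {
  tgt <- km_target(TOY, 5, name = "t",
                   genomic_offset = list(chrom = "chr5", start = 1000L,
                                         strand = "+"))
  calls <- call_target(tgt, flat_table(TOY_SNV), walker_config(count_threshold = 4))
  expect_equal(calls[[1]]$genomic_position, "chr5:1006")  # target pos 7
  tgt_m <- km_target(TOY, 5, name = "t",
                     genomic_offset = list(chrom = "chr5", start = 1000L,
                                           strand = "-"))
  calls_m <- call_target(tgt_m, flat_table(TOY_SNV), walker_config(count_threshold = 4))
  expect_equal(calls_m[[1]]$genomic_position, "chr5:994")
})

test_that("variant-mode targets confirm junctions by full k-mer coverage", {
  set.seed(31)
  a <- random_dna(40); b <- random_dna(40)
  junction <- paste0(substr(a, 21, 40), substr(b, 1, 20))  # 20+20 bp
  tgt <- km_target(junction, 9, name = "fusion", mode = "variant")
  cfg <- walker_config(count_threshold = 4)
  # reads from the fusion transcript: every junction k-mer present
  det <- interpret_variant_target(tgt, flat_table(junction, k = 9), cfg)
  expect_length(det, 1L)
  expect_equal(det[[1]]$call_type, "Reference")
  expect_equal(det[[1]]$notation, "variant-target detected")
  # reads from the two unfused partners only: junction-spanning k-mers absent
  expect_message(
    none <- interpret_variant_target(tgt, flat_table(c(a, b), k = 9), cfg),
    "not detected")
  expect_length(none, 0L)
  # junction present plus an extra insertion path: detected + Insertion call
  ins <- apply_mutation(junction, mut_insertion(20L, "TTCGAA"))
  both <- interpret_variant_target(tgt, flat_table(c(junction, ins), k = 9),
                                   cfg)
  expect_length(both, 2L)
  expect_equal(both[[1]]$notation, "variant-target detected")
  expect_true(both[[2]]$call_type %in% c("Insertion", "ITD", "I&I"))
})

test_that("known-event exclusions suppress matching calls", {
  tgt <- toy_target()
  tab <- flat_table(c(TOY, TOY_ITD))
  cfg <- walker_config(count_threshold = 4)
  all_calls <- call_target(tgt, tab, cfg)
  expect_length(all_calls, 1L)
  excl <- data.frame(position = all_calls[[1]]$position,
                     length = nchar(all_calls[[1]]$added))
  expect_length(call_target(tgt, tab, cfg, exclusions = excl), 1L)  # Reference remains
  expect_equal(call_target(tgt, tab, cfg, exclusions = excl)[[1]]$call_type,
               "Reference")
})

test_that("single injected events round-trip through reads at read scale", {
  set.seed(47)
  k <- 11L
  for (i in 1:6) {
    tmpl <- random_dna(90)
    site <- 40L
    spec <- switch(1L + (i %% 3),
                   mut_snv(site, setdiff(c("A", "C", "G", "T"),
                                         substr(tmpl, site, site))[1]),
                   mut_deletion(site, 4L),
                   mut_tandem_dup(site - 13L, 14L))
    mut <- apply_mutation(tmpl, spec)
    rs <- generate_reads(c(wt = tmpl, mut = mut), c(0.5, 0.5),
                         read_length = 30L, coverage = 80, error_rate = 0,
                         seed = i)
    tab <- count_reads(rs$reads, k = k, min_count = 2)
    tgt <- km_target(tmpl, k, name = "t")
    calls <- call_target(tgt, tab, walker_config())
    expect_length(calls, 1L)
    truth <- kmwalk:::normalize_event(tmpl, mut)
    expect_equal(calls[[1]]$position, truth$position)
    expect_equal(calls[[1]]$removed, truth$removed)
    expect_equal(calls[[1]]$added, truth$added)
  }
})
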
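#' Random DNA sequence
#'
#' @param n Length in bp.
#' @return A DNA string with i.i.d. uniform bases.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Mutation specifications
#'
#' Constructors for the event classes the simulator can inject into a
#' template: single-nucleotide variants, insertions, deletions, indels
#' (replacement of one string by another of different length), exact tandem
#' duplications, and fusions of two templates at stated breakpoints.
#'
#' @param position 1-based template coordinate. For `mut_snv` the base
#'   replaced; for `mut_insertion` the payload is inserted immediately after
#'   this base; for deletions/indels the first removed base.
#' @param base,payload Replacement base / inserted string.
#' @param length Number of template bases removed.
#' @param dup_start,dup_len The duplicated block `template[dup_start ..
#'   dup_start + dup_len - 1]`, copied immediately after its source.
#' @param partner,breakpoint_a,breakpoint_b Fusion partner sequence and
#'   breakpoints: the mutant is `template[1..breakpoint_a]` followed by
#'   `partner[breakpoint_b..]`.
#' @return A `mutation_spec` list.
#' @name mutation_spec
NULL

#' @rdname mutation_spec
#' @export
mut_snv <- function(position, base)
  structure(list(kind = "snv", position = position, base = base),
            class = "mutation_spec")

#' @rdname mutation_spec
#' @export
mut_insertion <- function(position, payload)
  structure(list(kind = "insertion", position = position, payload = payload),
            class = "mutation_spec")

#' @rdname mutation_spec
#' @export
mut_deletion <- function(position, length)
  structure(list(kind = "deletion", position = position, length = length),
            class = "mutation_spec")

#' @rdname mutation_spec
#' @export
mut_indel <- function(position, length, payload)
  structure(list(kind = "indel", position = position, length = length,
                 payload = payload), class = "mutation_spec")

#' @rdname mutation_spec
#' @export
mut_tandem_dup <- function(dup_start, dup_len)
  structure(list(kind = "tandem_dup", dup_start = dup_start,
                 dup_len = dup_len), class = "mutation_spec")

#' @rdname mutation_spec
#' @export
mut_fusion <- function(breakpoint_a, partner, breakpoint_b)
  structure(list(kind = "fusion", breakpoint_a = breakpoint_a,
                 partner = partner, breakpoint_b = breakpoint_b),
            class = "mutation_spec")

#' Apply a mutation specification to a template
#'
#' @param template DNA string.
#' @param spec A `mutation_spec`.
#' @return The mutant sequence.
#' @examples
#' apply_mutation("ACGTGCATTAGCC", mut_snv(7, "G"))
#' apply_mutation("ACGTGCATTAGCC", mut_tandem_dup(5, 4))
#' @export
apply_mutation <- function(template, spec) {
  stopifnot(inherits(spec, "mutation_spec"))
  n <- nchar(template)
  within <- function(p) {
    if (p < 1L || p > n) stop("position ", p, " outside template (1..", n, ")",
                              call. = FALSE)
    p
  }
  out <- switch(spec$kind,
    snv = {
      p <- within(spec$position)
      paste0(substr(template, 1L, p - 1L), spec$base,
             substr(template, p + 1L, n))
    },
    insertion = {
      p <- within(spec$position)
      paste0(substr(template, 1L, p), spec$payload,
             substr(template, p + 1L, n))
    },
    deletion = {
      p <- within(spec$position); within(p + spec$length - 1L)
      paste0(substr(template, 1L, p - 1L),
             substr(template, p + spec$length, n))
    },
    indel = {
      p <- within(spec$position); within(p + spec$length - 1L)
      paste0(substr(template, 1L, p - 1L), spec$payload,
             substr(template, p + spec$length, n))
    },
    tandem_dup = {
      p <- within(spec$dup_start)
      e <- within(p + spec$dup_len - 1L)
      paste0(substr(template, 1L, e), substr(template, p, e),
             substr(template, e + 1L, n))
    },
    fusion = {
      within(spec$breakpoint_a)
      if (spec$breakpoint_b < 1L || spec$breakpoint_b > nchar(spec$partner))
        stop("partner breakpoint outside partner sequence", call. = FALSE)
      paste0(substr(template, 1L, spec$breakpoint_a),
             substr(spec$partner, spec$breakpoint_b, nchar(spec$partner)))
    },
    stop("unknown mutation kind '", spec$kind, "'", call. = FALSE))
  if (out == template)
    stop("mutation leaves the template unchanged", call. = FALSE)
  out
}

#' Simulate reads from a haplotype mixture
#'
#' Draws uniformly positioned reads from each haplotype in proportion to its
#' fraction (per-haplotype read count = `round(coverage * fraction *
#' haplotype_length / read_length)`), each read on the forward or reverse
#' strand with probability 1/2, with i.i.d. substitution errors at
#' `error_rate`. Qualities are uniform Phred 40 ('I') unless a low-quality
#' tail is requested. Fully deterministic for a fixed seed.
#'
#' @param haplotypes Named character vector of haplotype sequences.
#' @param fractions Numeric vector summing to 1, parallel to `haplotypes`.
#' @param read_length Read length in bp (<= the shortest haplotype).
#' @param coverage Total coverage across haplotypes.
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#' @param low_quality_tail Number of 3' bases given Phred 2 ('#') quality,
#'   to exercise quality filtering (default 0).
#' @return A `km_readset`: list with `reads`, `qualities`, `truth`
#'   (per-read haplotype label) and `parameters`.
#' @export
generate_reads <- function(haplotypes, fractions = NULL, read_length = 50L,
                           coverage = 100, error_rate = 0.005, seed = 1L,
                           low_quality_tail = 0L) {
  if (is.null(fractions)) fractions <- rep(1 / length(haplotypes),
                                           length(haplotypes))
  stopifnot(length(fractions) == length(haplotypes),
            abs(sum(fractions) - 1) < 1e-8,
            read_length <= min(nchar(haplotypes)))
  if (is.null(names(haplotypes)))
    names(haplotypes) <- paste0("hap", seq_along(haplotypes))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  reads <- character(0); truth <- character(0)
  for (h in seq_along(haplotypes)) {
    seq_h <- haplotypes[[h]]
    len_h <- nchar(seq_h)
    n_reads <- round(coverage * fractions[h] * len_h / read_length)
    if (n_reads == 0L) next
    starts <- sample.int(len_h - read_length + 1L, n_reads, replace = TRUE)
    rd <- substring(seq_h, starts, starts + read_length - 1L)
    rev_strand <- stats::runif(n_reads) < 0.5
    rd[rev_strand] <- revcomp(rd[rev_strand])
    if (error_rate > 0) {
      rd <- vapply(rd, function(r) {
        hit <- which(stats::runif(read_length) < error_rate)
        if (length(hit) == 0L) return(r)
        ch <- strsplit(r, "")[[1L]]
        for (p in hit) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    reads <- c(reads, rd)
    truth <- c(truth, rep(names(haplotypes)[h], n_reads))
  }
  qual <- strrep("I", read_length)
  if (low_quality_tail > 0L)
    qual <- paste0(strrep("I", read_length - low_quality_tail),
                   strrep("#", low_quality_tail))
  structure(
    list(reads = reads, qualities = rep(qual, length(reads)), truth = truth,
         parameters = list(read_length = as.integer(read_length),
                           coverage = coverage, error_rate = error_rate,
                           seed = as.integer(seed))),
    class = "km_readset")
}

#' @export
print.km_readset <- function(x, ...) {
  cat(sprintf("simulated read set: %d reads of %d bp (seed %d)\n",
              length(x$reads), x$parameters$read_length, x$parameters$seed))
  print(table(x$truth))
  invisible(x)
}

#' Write a read set as FASTQ
#'
#' @param readset A `km_readset`.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(readset, path) {
  ids <- sprintf("read%06d|%s", seq_along(readset$reads), readset$truth)
  dna <- Biostrings::DNAStringSet(readset$reads)
  names(dna) <- ids
  Biostrings::writeXStringSet(dna, path, format = "fastq",
    qualities = Biostrings::BStringSet(readset$qualities))
  invisible(path)
}

write_fasta <- function(seqs, path) {
  dna <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

# prefix-anchored (position, removed, added) normalization of a
# template/mutant pair; records ground truth at generation time in the same
# canonical placement the caller reports
normalize_event <- function(ref, alt) {
  a <- utf8ToInt(ref); b <- utf8ToInt(alt)
  nmin <- min(length(a), length(b))
  neq <- which(a[seq_len(nmin)] != b[seq_len(nmin)])
  lp <- if (length(neq)) neq[1L] - 1L else nmin
  neq_s <- which(rev(a)[seq_len(nmin)] != rev(b)[seq_len(nmin)])
  ls <- if (length(neq_s)) neq_s[1L] - 1L else nmin
  if (lp + ls > nmin) ls <- nmin - lp
  list(position = lp + 1L,
       removed = substr(ref, lp + 1L, length(a) - ls),
       added = substr(alt, lp + 1L, length(b) - ls))
}

#' Names of the built-in simulation scenarios
#' @return Character vector of scenario names accepted by [scenario()].
#' @export
scenario_names <- function() {
  c("snv", "insertion_4bp", "deletion", "indel", "itd_short", "itd_long",
    "fusion", "low_vaf_4pct", "zero_coverage_downstream_snv")
}

#' Build a self-contained ground-truth scenario
#'
#' Each scenario draws a random template around a deterministic mutation
#' site, simulates reads from the wild-type/mutant haplotype mixture, and
#' records the expected call (type, left-aligned position, removed and added
#' strings) as ground truth. Defaults: k = 31, 50-bp reads, 200x total
#' coverage split equally between haplotypes, 0.5% substitution error.
#' `itd_long` duplicates 60 bp under 50-bp reads (duplications longer than
#' the read length remain detectable); `low_vaf_4pct` mixes the mutant at 4%
#' under deep coverage; `zero_coverage_downstream_snv` combines a
#' heterozygous ITD with a homozygous downstream SNV; `fusion` emits a
#' variant-mode junction target.
#'
#' @param name One of [scenario_names()].
#' @param seed Integer seed controlling template and reads.
#' @param dir Optional directory; when given, writes `targets.fa`,
#'   `reads.fq` and `truth.tsv` there.
#' @return List with `target` (a `km_target`), `readset`, `truth` (data
#'   frame with columns `call_type`, `position`, `removed`, `added`, `note`),
#'   `k`, and file `paths` when `dir` was given.
#' @export
scenario <- function(name, seed = 1L, dir = NULL) {
  name <- match.arg(name, scenario_names())
  k <- 31L
  set.seed(seed + 1000L)
  tmpl_len <- 240L
  site <- 110L  # mutation site comfortably > k from both ends
  tmpl <- random_dna(tmpl_len)
  put <- function(s, at, what)  # carve a fixed motif into the random template
    paste0(substr(s, 1L, at - 1L), what, substr(s, at + nchar(what), nchar(s)))
  mode <- "reference"
  read_length <- 50L; coverage <- 200; fractions <- c(wt = 0.5, mut = 0.5)
  note <- ""

  if (name == "snv") {
    tmpl <- put(tmpl, site, "A")
    spec <- mut_snv(site, "G")
  } else if (name == "insertion_4bp") {
    # NPM1-style 4-bp insertion; payload chosen unlike its flanks
    tmpl <- put(tmpl, site - 3L, "GGACTTAA")
    spec <- mut_insertion(site, "TCCG")
  } else if (name == "deletion") {
    tmpl <- put(tmpl, site - 1L, "CATTG")
    spec <- mut_deletion(site, 3L)
  } else if (name == "indel") {
    # the tg/GTCCGA replacement
    tmpl <- put(tmpl, site, "TG")
    tmpl <- put(tmpl, site - 1L, "A"); tmpl <- put(tmpl, site + 2L, "C")
    spec <- mut_indel(site, 2L, "GTCCGA")
  } else if (name == "itd_short") {
    spec <- mut_tandem_dup(site - 11L, 12L)
  } else if (name == "itd_long") {
    read_length <- 50L
    spec <- mut_tandem_dup(site - 59L, 60L)
  } else if (name == "fusion") {
    partner <- random_dna(tmpl_len)
    spec <- mut_fusion(120L, partner, 121L)
    mode <- "variant"
  } else if (name == "low_vaf_4pct") {
    tmpl_len <- 150L; site <- 70L
    tmpl <- random_dna(tmpl_len)
    tmpl <- put(tmpl, site, "TG")
    tmpl <- put(tmpl, site - 1L, "A"); tmpl <- put(tmpl, site + 2L, "C")
    spec <- mut_indel(site, 2L, "GTCCGA")
    read_length <- 75L; coverage <- 1500; fractions <- c(wt = 0.96, mut = 0.04)
    note <- "filtered at p=0.05, called at p=0.01"
  } else if (name == "zero_coverage_downstream_snv") {
    spec <- mut_tandem_dup(site - 11L, 12L)
  }

  if (name == "fusion") {
    fused <- apply_mutation(tmpl, spec)
    # variant-mode target: k bp + change on each side of the junction
    target_seq <- substr(fused, 120L - 49L, 120L + 50L)
    target <- km_target(target_seq, k, name = paste0("tgt_", name),
                        mode = "variant")
    haps <- c(fused = fused)
    fractions <- c(fused = 1)
    truth <- data.frame(call_type = "Reference", position = 0L,
                        removed = "", added = "",
                        note = "variant-target detected")
  } else if (name == "zero_coverage_downstream_snv") {
    snv_pos <- site + 40L
    itd_only <- apply_mutation(tmpl, spec)
    snv_spec <- mut_snv(snv_pos, if (substr(tmpl, snv_pos, snv_pos) == "C")
                                   "T" else "C")
    hap_snv <- apply_mutation(tmpl, snv_spec)                 # SNV only
    hap_both <- apply_mutation(itd_only, mut_snv(snv_pos + 12L,
                 substr(hap_snv, snv_pos, snv_pos)))          # ITD + SNV
    target <- km_target(tmpl, k, name = paste0("tgt_", name))
    haps <- c(snv = hap_snv, both = hap_both)
    fractions <- c(snv = 0.5, both = 0.5)
    ev_itd <- normalize_event(tmpl, itd_only)
    ev_snv <- normalize_event(tmpl, hap_snv)
    truth <- data.frame(
      call_type = c("ITD", "Substitution"),
      position = c(ev_itd$position, ev_snv$position),
      removed = c(ev_itd$removed, ev_snv$removed),
      added = c(ev_itd$added, ev_snv$added),
      note = c("flagged zero_coverage_target; hidden by default", ""))
  } else {
    mut <- apply_mutation(tmpl, spec)
    target <- km_target(tmpl, k, name = paste0("tgt_", name))
    haps <- c(wt = tmpl, mut = mut)
    names(fractions) <- names(haps)
    ev <- normalize_event(tmpl, mut)
    type <- classify_truth(spec, ev, tmpl)
    truth <- data.frame(call_type = type, position = ev$position,
                        removed = ev$removed, added = ev$added, note = note)
  }

  # embed every haplotype in shared transcript flanks: targets interrogate a
  # region inside an expressed transcript, so reads overhang both target ends
  # and coverage does not ramp down at the target boundary
  if (name != "fusion") {
    flank_l <- random_dna(read_length)
    flank_r <- random_dna(read_length)
    haps <- stats::setNames(paste0(flank_l, haps, flank_r), names(haps))
  }
  rs <- generate_reads(haps, fractions, read_length = read_length,
                       coverage = coverage, seed = seed)
  out <- list(name = name, target = target, readset = rs, truth = truth,
              k = k)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    tf <- file.path(dir, "targets.fa")
    hdr_seqs <- stats::setNames(target$sequence, target$name)
    write_fasta(hdr_seqs, tf)
    rf <- file.path(dir, "reads.fq")
    write_fastq(rs, rf)
    uf <- file.path(dir, "truth.tsv")
    utils::write.table(truth, uf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- list(targets = tf, reads = rf, truth = uf)
    out$mode <- target$mode
  }
  out
}

# expected call type for a single injected event
classify_truth <- function(spec, ev, tmpl) {
  switch(spec$kind,
    snv = "Substitution",
    deletion = "Deletion",
    tandem_dup = "ITD",
    indel = "Indel",
    insertion = classify_event(ev$removed, ev$added, tmpl, ev$position),
    stop("unexpected kind"))
}
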
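#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (alphabet ACGTN).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  # Biostrings wins on large batches; plain R avoids its per-call overhead
  # for the many tiny queries issued during walking
  if (length(x) >= 256L)
    return(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' Canonical form of a k-mer
#'
#' The canonical form is the lexicographically smaller of a k-mer and its
#' reverse complement (under A < C < G < T), collapsing the two sequencing
#' strands into a single key, as produced by Jellyfish's `-C` option.
#'
#' @param kmer Character vector of k-mers over \{A,C,G,T\}.
#' @return Character vector of canonical k-mers.
#' @examples
#' canonicalize("TTT")   # "AAA"
#' canonicalize("ACGT")  # palindrome, unchanged
#' @export
canonicalize <- function(kmer) {
  if (length(kmer) == 0L) return(character(0))
  if (any(grepl("[^ACGT]", kmer)))
    stop("k-mers must contain only A, C, G, T", call. = FALSE)
  rc <- revcomp(kmer)
  # pure-ASCII uppercase comparison; A<C<G<T holds in any locale
  ifelse(kmer <= rc, kmer, rc)
}

#' Construct a canonical k-mer count table
#'
#' @param counts Named integer vector: canonical k-mer -> occurrence count.
#' @param k k-mer length in bp; inferred from the keys when `NA`.
#' @param min_count Minimum stored count (Jellyfish `-L`); entries below it
#'   are dropped.
#' @param quality_threshold Minimum per-base Phred score for a k-mer window
#'   to have been counted; `0` means no quality filtering was applied.
#'   Recorded for provenance only.
#' @return An object of class `kmer_count_table`.
#' @export
kmer_count_table <- function(counts = integer(0), k = NA_integer_,
                             min_count = 2L, quality_threshold = 10L) {
  nm <- names(counts)
  counts <- as.integer(counts)
  names(counts) <- nm
  if (length(counts) > 0L) {
    if (is.null(names(counts)) || any(!nzchar(names(counts))))
      stop("counts must be a named vector keyed by k-mer", call. = FALSE)
    lens <- nchar(names(counts))
    if (is.na(k)) k <- lens[1L]
    if (any(lens != k))
      stop("all k-mers must have length k = ", k, call. = FALSE)
    counts <- counts[counts >= min_count]
  }
  env <- new.env(parent = emptyenv(), size = max(29L, length(counts)))
  if (length(counts) > 0L)
    list2env(as.list(counts), envir = env)
  structure(
    list(k = as.integer(k), counts = counts, min_count = as.integer(min_count),
         quality_threshold = as.integer(quality_threshold),
         canonical = TRUE, lookup = env),
    class = "kmer_count_table")
}

#' @export
print.kmer_count_table <- function(x, ...) {
  cat(sprintf("Canonical k-mer count table: k = %s, %d k-mers (min count %d)\n",
              ifelse(is.na(x$k), "unset", x$k), length(x$counts), x$min_count))
  if (length(x$counts) > 0L) {
    show <- utils::head(sort(x$counts, decreasing = TRUE), 5L)
    for (i in seq_along(show))
      cat(sprintf("  %s  %d\n", names(show)[i], show[i]))
    if (length(x$counts) > 5L) cat(sprintf("  ... and %d more\n", length(x$counts) - 5L))
  }
  invisible(x)
}

#' @export
length.kmer_count_table <- function(x) length(x$counts)

#' Query counts of k-mers (canonicalized before lookup)
#'
#' @param table A `kmer_count_table`.
#' @param kmers Character vector of k-mers (any strand).
#' @return Integer vector of counts, 0 for absent k-mers.
#' @export
kmer_count <- function(table, kmers) {
  if (length(kmers) == 0L) return(integer(0))
  can <- canonicalize(kmers)
  vapply(can, function(km) {
    v <- get0(km, envir = table$lookup, inherits = FALSE)
    if (is.null(v)) 0L else as.integer(v)
  }, integer(1), USE.NAMES = FALSE)
}

# sliding k-mer windows of one or more sequences, grouped by length for speed
sliding_kmers <- function(seqs, k) {
  lens <- nchar(seqs)
  out <- vector("list", length(seqs))
  for (L in unique(lens)) {
    idx <- which(lens == L)
    m <- L - k + 1L
    if (m < 1L) next
    starts <- seq_len(m)
    reps <- rep(seqs[idx], each = m)
    kms <- substring(reps, rep(starts, times = length(idx)),
                     rep(starts + k - 1L, times = length(idx)))
    out[idx] <- split(kms, rep(seq_along(idx), each = m))
  }
  out
}

#' Count canonical k-mers in a set of reads
#'
#' Every k-mer occurrence across all reads is counted after canonicalization
#' (both strands pooled). Windows containing an N are never counted. When
#' quality strings are supplied and `quality_threshold > 0`, any window
#' containing a base with Phred quality below the threshold is skipped
#' (mirrors Jellyfish `-Q`). Entries with a final count below `min_count`
#' are discarded (mirrors `-L`).
#'
#' @param reads Character vector of read sequences (may contain N).
#' @param k k-mer length (>= 2).
#' @param qualities Optional character vector of Phred+33 quality strings,
#'   parallel to `reads`.
#' @param min_count Minimum count to keep an entry (default 2).
#' @param quality_threshold Minimum per-base Phred score (default 10,
#'   the '+' character); 0 disables quality filtering.
#' @return A `kmer_count_table`.
#' @export
count_reads <- function(reads, k, qualities = NULL, min_count = 2L,
                        quality_threshold = 10L) {
  stopifnot(k >= 2L)
  k <- as.integer(k)
  reads <- toupper(as.character(reads))
  if (length(reads) > 0L && all(nchar(reads) < k)) {
    warning("k = ", k, " exceeds every read length; empty table", call. = FALSE)
    return(kmer_count_table(k = k, min_count = min_count,
                            quality_threshold = quality_threshold))
  }
  use_qual <- !is.null(qualities) && quality_threshold > 0L
  win <- sliding_kmers(reads, k)
  keep <- lapply(seq_along(reads), function(i) {
    kms <- win[[i]]
    if (is.null(kms) || length(kms) == 0L) return(character(0))
    ok <- !grepl("[^ACGT]", kms)
    if (use_qual) {
      phred <- utf8ToInt(qualities[[i]]) - 33L
      bad <- phred < quality_threshold
      if (any(bad)) {
        cb <- cumsum(bad)
        m <- length(kms)
        # window i spans bases i..i+k-1; any bad base disqualifies it
        nbad <- cb[seq_len(m) + k - 1L] - c(0L, cb)[seq_len(m)]
        ok <- ok & (nbad == 0L)
      }
    }
    kms[ok]
  })
  all_kmers <- unlist(keep, use.names = FALSE)
  if (length(all_kmers) == 0L)
    return(kmer_count_table(k = k, min_count = min_count,
                            quality_threshold = quality_threshold))
  tab <- table(canonicalize(all_kmers))
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  kmer_count_table(counts, k = k, min_count = min_count,
                   quality_threshold = quality_threshold)
}

#' Read a k-mer count table from a Jellyfish column dump
#'
#' Parses the two-column text format written by `jellyfish dump -c`
#' ("KMER COUNT" per line). Keys are canonicalized defensively: if a k-mer
#' and its reverse complement both appear, their counts are summed.
#'
#' @param path Path to the dump file.
#' @param min_count Minimum count to keep (applied after canonical merging).
#' @return A `kmer_count_table`.
#' @export
load_kmer_dump <- function(path, min_count = 1L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(kmer_count_table(k = NA_integer_, min_count = min_count))
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad) > 0L)
    stop("malformed dump line ", bad[1L], ": '", lines[bad[1L]], "'", call. = FALSE)
  kmers <- toupper(vapply(parts, `[`, character(1), 1L))
  cnts <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2L)))
  if (anyNA(cnts))
    stop("non-integer count on dump line ", which(is.na(cnts))[1L], call. = FALSE)
  lens <- nchar(kmers)
  if (any(lens != lens[1L])) {
    off <- which(lens != lens[1L])[1L]
    stop("heterogeneous k-mer length on dump line ", off,
         ": expected ", lens[1L], ", got ", lens[off], call. = FALSE)
  }
  can <- canonicalize(kmers)
  merged <- tapply(cnts, can, sum)
  counts <- as.integer(merged)
  names(counts) <- names(merged)
  kmer_count_table(counts, k = lens[1L], min_count = min_count)
}

#' Write a k-mer count table as a Jellyfish-style column dump
#'
#' One "KMER COUNT" pair per line, keys in lexicographic order so output is
#' byte-stable; `load_kmer_dump()` round-trips it exactly.
#'
#' @param table A `kmer_count_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_kmer_dump <- function(table, path) {
  stopifnot(inherits(table, "kmer_count_table"))
  keys <- sort(names(table$counts), method = "radix")
  writeLines(paste(keys, table$counts[keys]), path)
  invisible(path)
}

#' Read sequences (and qualities) from FASTA or FASTQ, gzip-transparent
#'
#' @param path Path to a FASTA or FASTQ file (optionally .gz).
#' @param format "auto" (by extension, falling back to content sniffing),
#'   "fasta" or "fastq".
#' @return List with `sequences` (character) and `qualities` (character or
#'   NULL for FASTA).
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    format <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE)) "fastq"
              else if (grepl("\\.(fa|fasta|fna)$", base, ignore.case = TRUE)) "fasta"
              else {
                con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
                first <- readLines(con, n = 1L)
                close(con)
                if (length(first) && startsWith(first, "@")) "fastq" else "fasta"
              }
  }
  if (format == "fastq") {
    # suppress the informational mcols-dropped warning on FASTQ input
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    list(sequences = as.character(x),
         qualities = as.character(Biostrings::quality(x)),
         names = names(x))
  } else {
    x <- Biostrings::readDNAStringSet(path)
    list(sequences = as.character(x), qualities = NULL, names = names(x))
  }
}
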
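#' Decompose a sequence into overlapping k-mers
#'
#' Returns the `len - k + 1` windows of length `k`, in order; consecutive
#' windows overlap by `k - 1` bases, so concatenating the first window with
#' the last base of each subsequent one reconstructs the sequence.
#'
#' @param sequence DNA string over \{A,C,G,T\}; N is not allowed in targets.
#' @param k Window length.
#' @return Character vector of k-mers.
#' @export
kmerize <- function(sequence, k) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (grepl("N", sequence, fixed = TRUE))
    stop("target sequence contains N; targets must be N-free", call. = FALSE)
  if (grepl("[^ACGT]", sequence))
    stop("target sequence contains non-ACGT characters", call. = FALSE)
  if (n < k)
    stop("sequence length ", n, " is shorter than k = ", k, call. = FALSE)
  starts <- seq_len(n - k + 1L)
  substring(sequence, starts, starts + k - 1L)
}

#' Check that a k-mer sequence forms a linear graph
#'
#' The k-mer graph of a target is linear precisely when all its k-mers are
#' pairwise distinct; repeated k-mers create ambiguous branch points that
#' make walking ill-defined.
#'
#' @param kmers Character vector of k-mers (from [kmerize()]).
#' @return List with `is_linear` (logical) and `first_repeated` (the first
#'   k-mer seen twice, or `NA` if linear).
#' @export
check_linearity <- function(kmers) {
  stopifnot(length(kmers) > 0L)
  dup <- duplicated(kmers)
  if (any(dup))
    list(is_linear = FALSE, first_repeated = kmers[which(dup)[1L]])
  else
    list(is_linear = TRUE, first_repeated = NA_character_)
}

#' Minimal target length for a variant site
#'
#' A target must flank the variant by at least k bp on each side so that its
#' first and last k-mers do not overlap the variant; the shortest such target
#' for a site spanning `variant_span` bases is `k + variant_span + k`.
#'
#' @param k k-mer length.
#' @param variant_span Width of the variant site in bp (>= 1).
#' @return Integer length in bp.
#' @examples
#' minimal_target_length(31, 3)  # 65, a codon-centred SNP target
#' @export
minimal_target_length <- function(k, variant_span) {
  stopifnot(k >= 2L, variant_span >= 1L)
  as.integer(k + variant_span + k)
}

# smallest k' in [from, nchar(seq)] at which all k-mers are distinct
min_linear_k <- function(sequence, from = 2L) {
  n <- nchar(sequence)
  for (kk in seq.int(min(from, n), n)) {
    if (!anyDuplicated(kmerize(sequence, kk))) return(as.integer(kk))
  }
  as.integer(n)
}

parse_genomic_offset <- function(header) {
  # header dialect: "name|chr:start:strand", 1-based start, forward strand coords
  parts <- strsplit(header, "|", fixed = TRUE)[[1L]]
  name <- parts[1L]
  offset <- NULL
  if (length(parts) >= 2L) {
    meta <- strsplit(parts[2L], ":", fixed = TRUE)[[1L]]
    start <- suppressWarnings(as.integer(meta[2L]))
    if (length(meta) == 3L && !is.na(start) && meta[3L] %in% c("+", "-")) {
      offset <- list(chrom = meta[1L], start = start, strand = meta[3L])
    } else {
      warning("malformed genomic-offset metadata in header '", header,
              "'; ignored", call. = FALSE)
    }
  }
  list(name = name, offset = offset)
}

#' Construct a target sequence object
#'
#' @param sequence DNA string.
#' @param k k-mer length.
#' @param name Target identifier.
#' @param mode `"reference"` (sequence copies the reference; alternative walks
#'   are variants) or `"variant"` (sequence encodes an expected mutation such
#'   as a fusion junction; full k-mer coverage confirms it).
#' @param genomic_offset Optional list `(chrom, start, strand)` locating
#'   target base 1 on the genome (1-based, forward-strand coordinates).
#' @return An object of class `km_target`.
#' @export
km_target <- function(sequence, k, name = "target",
                      mode = c("reference", "variant"),
                      genomic_offset = NULL) {
  mode <- match.arg(mode)
  sequence <- toupper(sequence)
  k <- as.integer(k)
  if (nchar(sequence) < 2L * k - 1L)
    stop("target '", name, "' is shorter than 2k-1 = ", 2L * k - 1L,
         " bp; its first and last k-mers would overlap every internal position",
         call. = FALSE)
  kmers <- kmerize(sequence, k)
  lin <- check_linearity(kmers)
  if (!lin$is_linear) {
    stop("target '", name, "' is not linear at k = ", k,
         ": k-mer '", lin$first_repeated, "' repeats; smallest linearizing k is ",
         min_linear_k(sequence, from = k + 1L), call. = FALSE)
  }
  structure(
    list(name = name, sequence = sequence, k = k, kmers = kmers,
         mode = mode, genomic_offset = genomic_offset),
    class = "km_target")
}

#' @export
print.km_target <- function(x, ...) {
  cat(sprintf("km target '%s' (%s mode): %d bp, %d k-mers at k = %d\n",
              x$name, x$mode, nchar(x$sequence), length(x$kmers), x$k))
  if (!is.null(x$genomic_offset))
    cat(sprintf("  genomic offset: %s:%d:%s\n", x$genomic_offset$chrom,
                x$genomic_offset$start, x$genomic_offset$strand))
  invisible(x)
}

#' Load target sequences from a FASTA file
#'
#' Each record is k-merized and linearity-checked; a record that is not
#' linear at the requested k is rejected with an error naming the repeated
#' k-mer and the smallest k that would linearize it. Header metadata of the
#' form `name|chr:start:strand` populates the genomic offset.
#'
#' @param path FASTA file of target sequences.
#' @param k k-mer length.
#' @param mode Target mode applied to all records ("reference" or "variant").
#' @return List of `km_target` objects.
#' @export
load_targets <- function(path, k, mode = c("reference", "variant")) {
  mode <- match.arg(mode)
  fa <- Biostrings::readDNAStringSet(path)
  if (length(fa) == 0L) stop("no records in ", path, call. = FALSE)
  lapply(seq_along(fa), function(i) {
    hdr <- parse_genomic_offset(names(fa)[i])
    km_target(as.character(fa[[i]]), k = k, name = hdr$name, mode = mode,
              genomic_offset = hdr$offset)
  })
}

#' Audit FASTA records for linearity at a given k
#'
#' For each record reports its length, whether its k-mer graph is linear at
#' `k`, and the smallest k at which it becomes linear (capped at the record
#' length). The fraction of linear records summarizes how much of a sequence
#' catalogue is usable as targets at this k.
#'
#' @param path FASTA file.
#' @param k k-mer length to audit at.
#' @return Data frame with columns `name`, `length`, `linear_at_k`,
#'   `min_linear_k`; the fraction linear is attached as attribute
#'   `fraction_linear`.
#' @export
audit_targets <- function(path, k) {
  fa <- Biostrings::readDNAStringSet(path)
  rows <- lapply(seq_along(fa), function(i) {
    s <- toupper(as.character(fa[[i]]))
    n <- nchar(s)
    if (n < k) {
      return(data.frame(name = names(fa)[i], length = n,
                        linear_at_k = NA, min_linear_k = NA_integer_))
    }
    lin <- !anyDuplicated(kmerize(s, k))
    data.frame(name = names(fa)[i], length = n, linear_at_k = lin,
               min_linear_k = if (lin) min_linear_k(s, from = 2L)
                              else min_linear_k(s, from = k + 1L))
  })
  out <- do.call(rbind, rows)
  attr(out, "fraction_linear") <- mean(out$linear_at_k, na.rm = TRUE)
  out
}
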
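# Independent brute-force oracles. Deliberately written with naive loops and
# their own string primitives so they share no code with the package.

naive_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

naive_canonical <- function(x) {
  rc <- naive_revcomp(x)
  ifelse(x <= rc, x, rc)
}

# O(n*k) recount: loop over reads and windows, skip N windows, canonicalize
# by direct comparison, then threshold.
naive_count_reads <- function(reads, k, min_count = 1L) {
  acc <- list()
  for (r in reads) {
    n <- nchar(r)
    if (n < k) next
    for (i in seq_len(n - k + 1L)) {
      w <- substr(r, i, i + k - 1L)
      if (grepl("[^ACGT]", w)) next
      can <- naive_canonical(w)
      acc[[can]] <- (acc[[can]] %||% 0L) + 1L
    }
  }
  v <- unlist(acc)
  if (is.null(v)) return(integer(0))
  v <- v[v >= min_count]
  v[order(names(v), method = "radix")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic comparison form: named count vector ordered by k-mer
by_kmer <- function(v) v[order(names(v), method = "radix")]

# Exhaustive enumeration of every bounded walk between target k-mers under
# the count/sibling-ratio/step constraints; returns the sorted set of
# assembled sequences (deduplicated), for comparison with explore().
oracle_walks <- function(target_seq, k, counts, c_thr, p_thr, s_max) {
  n <- nchar(target_seq) - k + 1L
  tk <- vapply(seq_len(n), function(i) substr(target_seq, i, i + k - 1L),
               character(1))
  cnt <- function(km) {
    can <- naive_canonical(km)
    if (can %in% names(counts)) unname(counts[[can]]) else 0L
  }
  out <- character(0)
  assemble <- function(div, rejoin, branch) {
    path <- c(tk[seq_len(div)], branch, tk[seq.int(rejoin, n)])
    paste0(path[1L], paste(vapply(path[-1L], function(x) substr(x, k, k),
                                  character(1)), collapse = ""))
  }
  recurse <- function(i, branch) {
    tip <- if (length(branch)) branch[length(branch)] else tk[i]
    cand <- paste0(substr(tip, 2L, k), c("A", "C", "G", "T"))
    cc <- vapply(cand, cnt, numeric(1))
    for (j in 1:4) {
      if (!(cc[j] > c_thr && cc[j] > p_thr * max(cc[-j]))) next
      km <- cand[j]
      if (length(branch) == 0L && i < n && km == tk[i + 1L]) next
      if (km %in% tk) {
        out[length(out) + 1L] <<- assemble(i, match(km, tk), branch)
      } else if (length(branch) + 1L <= s_max) {
        recurse(i, c(branch, km))
      }
    }
  }
  for (i in seq_len(n)) recurse(i, character(0))
  sort(unique(out))
}
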
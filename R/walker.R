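#' Walker configuration
#'
#' Thresholds governing the depth-first exploration of alternative paths.
#'
#' @param count_threshold Minimum k-mer count, exclusive, to extend a branch
#'   (the `c` threshold; default 5). A branch k-mer must have count
#'   strictly greater than this.
#' @param ratio_threshold Branch-ratio threshold as a fraction (the `P`
#'   threshold; default 0.05). At each node a candidate extension survives
#'   only if its count exceeds `ratio_threshold` times the largest count
#'   among the competing sibling extensions at that node.
#' @param max_steps Maximum branch length in k-mer extensions before a branch
#'   that has not rejoined the target is abandoned (the `s` limit;
#'   default 500).
#' @param max_walks Safety cap on walks emitted per target (default 1000);
#'   exceeding it truncates with a warning and signals a repeat-rich target.
#' @return An object of class `walker_config`.
#' @export
walker_config <- function(count_threshold = 5, ratio_threshold = 0.05,
                          max_steps = 500L, max_walks = 1000L) {
  stopifnot(count_threshold >= 0, ratio_threshold >= 0, ratio_threshold < 1,
            max_steps >= 1L)
  structure(list(count_threshold = count_threshold,
                 ratio_threshold = ratio_threshold,
                 max_steps = as.integer(max_steps),
                 max_walks = as.integer(max_walks)),
            class = "walker_config")
}

#' @export
print.walker_config <- function(x, ...) {
  cat(sprintf("walker config: c = %g, P = %g, s = %d, max_walks = %d\n",
              x$count_threshold, x$ratio_threshold, x$max_steps, x$max_walks))
  invisible(x)
}

#' Enumerate the four suffix extensions of a k-mer
#'
#' Candidates are `kmer[2:k]` followed by each base, in fixed order
#' A, C, G, T; counts are canonical-table lookups (0 when absent).
#'
#' @param kmer A k-mer of the table's k.
#' @param table A `kmer_count_table`.
#' @return Data frame with columns `kmer` and `count`, four rows.
#' @export
extensions <- function(kmer, table) {
  stopifnot(nchar(kmer) == table$k)
  cand <- paste0(substr(kmer, 2L, table$k), c("A", "C", "G", "T"))
  data.frame(kmer = cand, count = kmer_count(table, cand))
}

# internal: construct an alt_walk record
alt_walk <- function(target, divergence_index, rejoin_index, branch_kmers, table) {
  path <- c(target$kmers[seq_len(divergence_index)], branch_kmers,
            target$kmers[seq.int(rejoin_index, length(target$kmers))])
  assembled <- paste0(path[1L],
                      paste(substr(path[-1L], target$k, target$k), collapse = ""))
  structure(
    list(divergence_index = divergence_index, rejoin_index = rejoin_index,
         branch_kmers = branch_kmers, assembled_sequence = assembled,
         kmer_counts = kmer_count(table, path), path = path),
    class = "alt_walk")
}

#' @export
print.alt_walk <- function(x, ...) {
  cat(sprintf("alt walk: diverges at k-mer %d, rejoins at %d (%d branch k-mers)\n",
              x$divergence_index, x$rejoin_index, length(x$branch_kmers)))
  cat("  ", x$assembled_sequence, "\n")
  invisible(x)
}

# survivors among 4 candidate extensions: count > c and
# count > P * max(count of the competing siblings at this node)
surviving_extensions <- function(ext, cfg) {
  counts <- ext$count
  other_max <- vapply(seq_len(4L), function(j) max(counts[-j]), numeric(1))
  which(counts > cfg$count_threshold &
        counts > cfg$ratio_threshold * other_max)
}

#' Explore a count table for alternative walks off a target
#'
#' Depth-first search seeded at every target k-mer: each extension whose next
#' k-mer is not the target's own continuation opens a branch, extended only
#' through k-mers passing the count and sibling-ratio thresholds. A branch
#' ends successfully on first touching any target k-mer (upstream rejoins,
#' as created by tandem duplications, are allowed) and is abandoned after
#' `max_steps` extensions. Walks are deduplicated by assembled sequence. An
#' empty result means no variant evidence for this target.
#'
#' @param target A `km_target` (linear at the table's k).
#' @param table A `kmer_count_table` with `table$k == target$k`.
#' @param cfg A `walker_config`.
#' @return List of `alt_walk` objects (possibly empty).
#' @export
explore <- function(target, table, cfg = walker_config()) {
  stopifnot(inherits(target, "km_target"), inherits(table, "kmer_count_table"))
  if (!is.na(table$k) && table$k != target$k)
    stop("k mismatch: target k = ", target$k, ", table k = ", table$k,
         call. = FALSE)
  tk <- target$kmers
  n <- length(tk)
  t_index <- seq_len(n)
  names(t_index) <- tk
  walks <- list()
  seen <- character(0)
  truncated <- FALSE

  emit <- function(div, rejoin, branch) {
    w <- alt_walk(target, div, rejoin, branch, table)
    if (!(w$assembled_sequence %in% seen)) {
      seen <<- c(seen, w$assembled_sequence)
      walks[[length(walks) + 1L]] <<- w
    }
  }

  for (i in seq_len(n)) {
    ext <- extensions(tk[i], table)
    surv <- surviving_extensions(ext, cfg)
    next_target <- if (i < n) tk[i + 1L] else NA_character_
    for (j in surv) {
      km0 <- ext$kmer[j]
      if (!is.na(next_target) && km0 == next_target) next  # target's own path
      # depth-first over branch extensions; stack entries are k-mer paths
      stack <- list(km0)
      while (length(stack) > 0L) {
        if (truncated) break
        path <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        tip <- path[length(path)]
        hit <- t_index[tip]
        if (!is.na(hit)) {
          # first touch of a target k-mer ends the branch
          if (length(walks) >= cfg$max_walks) {
            truncated <- TRUE
            break
          }
          emit(i, unname(hit), path[-length(path)])
          next
        }
        if (length(path) >= cfg$max_steps + 1L) next  # abandoned
        e2 <- extensions(tip, table)
        s2 <- surviving_extensions(e2, cfg)
        # push in reverse so A,C,G,T order is explored first
        for (jj in rev(s2))
          stack[[length(stack) + 1L]] <- c(path, e2$kmer[jj])
      }
      if (truncated) break
    }
    if (truncated) break
  }
  if (truncated)
    warning("walk cap (max_walks = ", cfg$max_walks, ") reached for target '",
            target$name, "'; output truncated -- the target is likely ",
            "repeat-rich at this k", call. = FALSE)
  walks
}
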
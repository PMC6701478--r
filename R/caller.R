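#' Reduce a reference/alternative sequence pair to its variant
#'
#' Anchor-based diff: strip the longest common prefix and longest common
#' suffix, clipping the suffix when the two would overlap so the prefix
#' anchor wins. Ambiguous placements (events inside repeats) thus collapse to
#' the single placement adjacent to the end of the matching prefix -- a
#' tandem duplication is reported immediately after its copied block, which
#' is what the flank-based insertion subtyping expects.
#'
#' @param ref_sequence Reference (target) sequence.
#' @param alt_sequence Assembled alternative sequence; shares its first and
#'   last k characters with the reference by walk construction.
#' @return List with `position` (1-based coordinate of the first affected
#'   reference base; 0 for identical sequences), `removed`, `added`.
#' @export
trim_to_variant <- function(ref_sequence, alt_sequence) {
  if (ref_sequence == alt_sequence)
    return(list(position = 0L, removed = "", added = ""))
  a <- utf8ToInt(ref_sequence)
  b <- utf8ToInt(alt_sequence)
  nmin <- min(length(a), length(b))
  neq <- which(a[seq_len(nmin)] != b[seq_len(nmin)])
  lp <- if (length(neq)) neq[1L] - 1L else nmin
  neq_s <- which(rev(a)[seq_len(nmin)] != rev(b)[seq_len(nmin)])
  ls <- if (length(neq_s)) neq_s[1L] - 1L else nmin
  if (lp + ls > nmin) ls <- nmin - lp  # prefix anchor wins the overlap
  list(position = lp + 1L,
       removed = substr(ref_sequence, lp + 1L, length(a) - ls),
       added = substr(alt_sequence, lp + 1L, length(b) - ls))
}

# ungapped positionwise identity of two equal-length strings
ungapped_identity <- function(x, y) {
  mean(utf8ToInt(x) == utf8ToInt(y))
}

#' Classify a pure insertion as ITD, I&I or plain Insertion
#'
#' The inserted string is compared with the equally long stretches of target
#' sequence immediately upstream and downstream of the insertion point. An
#' exact match to either flank is an internal tandem duplication (ITD); more
#' than 50% ungapped positionwise identity to the better-matching flank is an
#' I&I (Insertion and ITD); anything else is a plain Insertion.
#'
#' @param added Inserted string (non-empty).
#' @param ref_sequence Target sequence.
#' @param position 1-based coordinate of the first reference base after the
#'   insertion point (as returned by [trim_to_variant()]).
#' @return One of `"ITD"`, `"I&I"`, `"Insertion"`.
#' @export
classify_insertion <- function(added, ref_sequence, position) {
  stopifnot(nzchar(added))
  len <- nchar(added)
  n <- nchar(ref_sequence)
  up <- if (position - len >= 1L)
    substr(ref_sequence, position - len, position - 1L) else NA_character_
  down <- if (position + len - 1L <= n)
    substr(ref_sequence, position, position + len - 1L) else NA_character_
  flanks <- c(up, down)
  flanks <- flanks[!is.na(flanks)]
  if (length(flanks) == 0L) return("Insertion")
  if (any(flanks == added)) return("ITD")
  ident <- max(vapply(flanks, ungapped_identity, numeric(1), y = added))
  if (ident > 0.5) "I&I" else "Insertion"
}

#' Classify a (removed, added) pair as a variant type
#'
#' Total mapping: empty/empty is Reference; equal non-zero lengths are a
#' Substitution; insertion-only pairs are refined by [classify_insertion()];
#' deletion-only pairs are Deletions; both-non-empty pairs (an insertion
#' adjacent to a deletion) are Indels.
#'
#' @param removed,added Strings from [trim_to_variant()].
#' @param ref_sequence Target sequence (used for insertion subtyping).
#' @param position 1-based variant position.
#' @return One of `"Reference"`, `"Substitution"`, `"Deletion"`,
#'   `"Insertion"`, `"ITD"`, `"I&I"`, `"Indel"`.
#' @export
classify_event <- function(removed, added, ref_sequence, position) {
  nr <- nchar(removed); na <- nchar(added)
  if (nr == 0L && na == 0L) return("Reference")
  if (nr == na) return("Substitution")
  if (nr == 0L) return(classify_insertion(added, ref_sequence, position))
  if (na == 0L) return("Deletion")
  "Indel"
}

#' Quantify an alternative walk
#'
#' The local coverage ratio contrasts the mean count of the walk's branch
#' k-mers with the mean count of the target k-mers the walk replaces (the
#' target k-mers strictly between divergence and rejoin; when that span is
#' empty, as for upstream-rejoining duplications, the two target k-mers
#' adjacent to the junction). `ratio = alt / (alt + ref)`, defined as 1 when
#' the reference span has zero coverage.
#'
#' @param walk An `alt_walk` with a non-empty branch.
#' @param target The `km_target` walked.
#' @param table The `kmer_count_table`.
#' @return List with `ratio` (in \[0, 1\]) and `min_coverage` (minimum
#'   k-mer count along the assembled walk).
#' @export
quantify <- function(walk, target, table) {
  branch_counts <- if (length(walk$branch_kmers) > 0L)
    kmer_count(table, walk$branch_kmers)
  else  # degenerate branch (pure repeat-mediated jump): junction-flanking path k-mers
    walk$kmer_counts[c(walk$divergence_index,
                       min(walk$divergence_index + 1L, length(walk$path)))]
  alt_mean <- mean(branch_counts)
  i0 <- walk$divergence_index + 1L
  i1 <- walk$rejoin_index - 1L
  ref_idx <- if (i0 <= i1) seq.int(i0, i1)
             else c(walk$divergence_index, walk$rejoin_index)
  ref_mean <- mean(kmer_count(table, target$kmers[ref_idx]))
  ratio <- if (ref_mean == 0) 1 else alt_mean / (alt_mean + ref_mean)
  list(ratio = ratio, min_coverage = min(walk$kmer_counts))
}

#' Select a minimal set of walks covering all observed branch edges
#'
#' Edges between consecutive k-mers of the target path carry weight 0.01 and
#' branch edges weight 1.0, so walk weight prefers minimal-branch
#' explanations. Walks are selected greedily in increasing total weight
#' (ties by assembled sequence) until every branch edge observed in any walk
#' is covered by a selected walk; unselected walks are discarded.
#'
#' @param walks List of deduplicated `alt_walk` objects.
#' @param target The `km_target`.
#' @return Ordered sublist of `walks`.
#' @export
select_walks <- function(walks, target) {
  if (length(walks) <= 1L) return(walks)
  tk <- target$kmers
  target_edges <- paste(tk[-length(tk)], tk[-1L])
  edge_sets <- lapply(walks, function(w) {
    p <- w$path
    paste(p[-length(p)], p[-1L])
  })
  weights <- vapply(edge_sets, function(e) {
    is_t <- e %in% target_edges
    sum(ifelse(is_t, 0.01, 1.0))
  }, numeric(1))
  seqs <- vapply(walks, `[[`, character(1), "assembled_sequence")
  ord <- order(weights, seqs)
  branch_edges <- unique(unlist(lapply(edge_sets, function(e)
    setdiff(e, target_edges))))
  covered <- character(0)
  selected <- integer(0)
  for (i in ord) {
    new_edges <- setdiff(setdiff(edge_sets[[i]], target_edges), covered)
    if (length(new_edges) > 0L) {
      selected <- c(selected, i)
      covered <- c(covered, new_edges)
      if (length(covered) >= length(branch_edges)) break
    }
  }
  walks[selected]
}

km_call <- function(target, call_type, position = 0L, removed = "",
                    added = "", ratio = 1, min_coverage = 0L,
                    alt_sequence = target$sequence, walk = NULL,
                    filters = character(0), note = NA_character_) {
  genomic <- NA_character_
  if (!is.null(target$genomic_offset) && position > 0L) {
    off <- target$genomic_offset
    gp <- if (off$strand == "+") off$start + position - 1L
          else off$start - (position - 1L)
    genomic <- sprintf("%s:%d", off$chrom, gp)
  }
  structure(
    list(target_name = target$name, call_type = call_type,
         position = as.integer(position), genomic_position = genomic,
         removed = removed, added = added,
         notation = if (is.na(note)) paste0(tolower(removed), "/", toupper(added))
                    else note,
         alt_sequence = alt_sequence, ratio = ratio,
         min_coverage = as.integer(min_coverage),
         filters = filters, walk = walk),
    class = "km_call")
}

#' @export
print.km_call <- function(x, ...) {
  cat(sprintf("%s  %s @%d  %s  ratio=%.4f  min_cov=%d  [%s]\n",
              x$target_name, x$call_type, x$position, x$notation, x$ratio,
              x$min_coverage,
              if (length(x$filters)) paste(x$filters, collapse = ",") else "PASS"))
  invisible(x)
}

#' Attach filter flags to variant calls
#'
#' `zero_coverage_target` flags a call whose target path outside the walk's
#' divergent span (before the divergence point or after the rejoin point)
#' contains a k-mer with zero coverage: such walks can arise from a related
#' transcript sharing subsequences with the target, though they also hide
#' real events co-occurring with a homozygous SNV elsewhere on the target.
#' `below_ratio` flags calls whose local coverage ratio falls below the
#' `ratio_threshold` (P). By default flagged calls are excluded from output;
#' `keep_filtered` retains them with their flags visible.
#'
#' @param calls List of `km_call` objects carrying their walks.
#' @param target The `km_target`.
#' @param table The `kmer_count_table`.
#' @param cfg A `walker_config`.
#' @return The calls with `filters` populated.
#' @export
apply_filters <- function(calls, target, table, cfg = walker_config()) {
  n <- length(target$kmers)
  tcounts <- kmer_count(table, target$kmers)
  lapply(calls, function(cl) {
    if (cl$call_type == "Reference" || is.null(cl$walk)) return(cl)
    w <- cl$walk
    outside <- unique(c(seq_len(w$divergence_index),
                        seq.int(w$rejoin_index, n)))
    if (any(tcounts[outside] == 0L))
      cl$filters <- c(cl$filters, "zero_coverage_target")
    if (cl$ratio < cfg$ratio_threshold)
      cl$filters <- c(cl$filters, "below_ratio")
    cl
  })
}

walk_to_call <- function(walk, target, table) {
  tv <- trim_to_variant(target$sequence, walk$assembled_sequence)
  type <- classify_event(tv$removed, tv$added, target$sequence, tv$position)
  q <- quantify(walk, target, table)
  km_call(target, type, position = tv$position, removed = tv$removed,
          added = tv$added, ratio = q$ratio, min_coverage = q$min_coverage,
          alt_sequence = walk$assembled_sequence, walk = walk)
}

#' Call variants on one reference-mode target
#'
#' Runs the full pipeline: explore alternative walks, select a covering
#' subset, diff, classify and quantify each, then filter. When no walk
#' survives and the target path is fully covered, a single Reference call is
#' emitted; when the target path itself has zero-coverage k-mers and there
#' are no walks, nothing is emitted (the target is not expressed in the
#' sample).
#'
#' @param target A `km_target` in reference mode.
#' @param table A `kmer_count_table`.
#' @param cfg A `walker_config`.
#' @param keep_filtered Keep flagged calls in the output (default drops them).
#' @param exclusions Optional data frame or list of `(position, length)`
#'   pairs of known events to suppress (e.g., intronic insertions retained
#'   in the target design); a call is dropped when its position and added
#'   length both match an exclusion.
#' @return List of `km_call` objects (possibly empty).
#' @export
call_target <- function(target, table, cfg = walker_config(),
                        keep_filtered = FALSE, exclusions = NULL) {
  walks <- explore(target, table, cfg)
  walks <- select_walks(walks, target)
  calls <- lapply(walks, walk_to_call, target = target, table = table)
  calls <- apply_filters(calls, target, table, cfg)
  if (!is.null(exclusions)) {
    excl <- as.data.frame(exclusions)
    calls <- Filter(function(cl) {
      !any(excl$position == cl$position & excl$length == nchar(cl$added))
    }, calls)
  }
  if (!keep_filtered)
    calls <- Filter(function(cl) length(cl$filters) == 0L, calls)
  if (length(calls) == 0L) {
    tcounts <- kmer_count(table, target$kmers)
    if (all(tcounts > 0L)) {
      calls <- list(km_call(target, "Reference", ratio = 1,
                            min_coverage = min(tcounts)))
    } else {
      message("target '", target$name, "' not expressed (", sum(tcounts == 0L),
              " of ", length(tcounts), " target k-mers have zero coverage)")
    }
  }
  calls
}

#' Interpret a variant-mode target
#'
#' A variant target encodes an expected rearrangement (e.g., a fusion
#' junction); the event is confirmed when every target k-mer is present in
#' the sample's count table, in which case a Reference-type call annotated
#' "variant-target detected" is emitted. Alternative walks are additionally
#' reported through the normal pipeline -- against a variant target they
#' represent the wild type or alternative isoforms.
#'
#' @inheritParams call_target
#' @return List of `km_call` objects; empty when the expected variant is not
#'   detected and no alternative path exists.
#' @export
interpret_variant_target <- function(target, table, cfg = walker_config(),
                                     keep_filtered = FALSE) {
  tcounts <- kmer_count(table, target$kmers)
  detected <- all(tcounts > 0L)
  walks <- explore(target, table, cfg)
  walks <- select_walks(walks, target)
  calls <- lapply(walks, walk_to_call, target = target, table = table)
  calls <- apply_filters(calls, target, table, cfg)
  if (!keep_filtered)
    calls <- Filter(function(cl) length(cl$filters) == 0L, calls)
  if (detected) {
    calls <- c(list(km_call(target, "Reference", ratio = 1,
                            min_coverage = min(tcounts),
                            note = "variant-target detected")),
               calls)
  } else if (length(calls) == 0L) {
    message("variant target '", target$name, "' not detected (",
            sum(tcounts == 0L), " of ", length(tcounts),
            " junction k-mers have zero coverage)")
  }
  calls
}
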
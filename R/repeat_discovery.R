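# Novel-repeat discovery from element self-alignment: all-vs-all local
# alignment of (pericentromere-enriched) element sequences, single-linkage
# clustering of the repeated intervals, occurrence filtering, counting of
# merged hits on the pericentromere sequences, and known-repeat exclusion.

#' Cluster repeated intervals across element sequences
#'
#' All-vs-all local alignment of the element sequences (both strands); each
#' hit contributes its query and target intervals, which are single-linkage
#' clustered: the two intervals of a hit are linked, and intervals on the
#' same element record are linked when they overlap reciprocally by at
#' least `reciprocal`.  Each cluster's representative is its
#' highest-scoring interval and `self_occurrences` counts the distinct
#' element records the cluster touches (duplicated input records count
#' twice).
#'
#' @param element_seqs named character vector of element sequences (>= 2)
#' @param min_identity minimum hit identity (default 0.8)
#' @param min_length minimum hit length in bp (default 100)
#' @param reciprocal reciprocal-overlap fraction for linking (default 0.5)
#' @param scoring an [align_scoring()]
#' @return a `candidate_repeats` data.frame: `unit_id`, `seq`, `length`,
#'   `self_occurrences`, `rep_element`, `rep_start`, `rep_end`, `score`
#' @export
self_cluster <- function(element_seqs, min_identity = 0.8, min_length = 100L,
                         reciprocal = 0.5, scoring = align_scoring()) {
  n <- length(element_seqs)
  if (n < 2) stop("need at least 2 element sequences")
  if (is.null(names(element_seqs)))
    names(element_seqs) <- sprintf("elem%04d", seq_len(n))
  # collect intervals: (element index, start, end, score); hits link pairs.
  # a shared-kmer prescreen skips strands with no common seed material
  # (fewer than min_length - seed_k + 1 shared k-mers can never yield a hit
  # of min_length exact-matching bases, and random 5 kb pairs share none)
  shared <- cpp_pair_shared(unname(element_seqs), scoring$seed_k)
  min_shared <- 3L
  rc <- revcomp(element_seqs)
  qlen <- nchar(element_seqs)
  elem_l <- list(); s_l <- list(); e_l <- list(); sc_l <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      for (strand in c("+", "-")) {
        if (strand == "+" && shared$pp[i, j] < min_shared) next
        if (strand == "-" && shared$rp[i, j] < min_shared) next
        qi <- if (strand == "+") element_seqs[[i]] else rc[[i]]
        h <- cpp_local_align(qi, element_seqs[[j]], scoring$seed_k,
                             min_identity, as.integer(min_length),
                             scoring$match, scoring$mismatch,
                             scoring$gap_open, scoring$gap_ext,
                             scoring$diag_join, scoring$gap_join,
                             scoring$window_pad, scoring$band_pad)
        if (nrow(h) == 0L) next
        qs <- h$qstart; qe <- h$qend
        if (strand == "-") { tmp <- qlen[i] - qe; qe <- qlen[i] - qs; qs <- tmp }
        k <- length(elem_l) + 1L
        elem_l[[k]] <- rep(c(i, j), nrow(h))
        s_l[[k]] <- as.vector(rbind(qs, h$tstart))
        e_l[[k]] <- as.vector(rbind(qe, h$tend))
        sc_l[[k]] <- rep(h$score, each = 2L)
      }
    }
  }
  elem <- unlist(elem_l); s <- unlist(s_l); e <- unlist(e_l)
  sc <- unlist(sc_l)
  m <- length(elem)
  links <- if (m > 0) lapply(seq_len(m / 2L), function(x)
    c(2L * x - 1L, 2L * x)) else list()
  if (m == 0)
    return(structure(data.frame(unit_id = character(), seq = character(),
                                length = integer(),
                                self_occurrences = integer(),
                                rep_element = character(),
                                rep_start = integer(), rep_end = integer(),
                                score = integer()),
                     class = c("candidate_repeats", "data.frame")))
  parent <- seq_len(m)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[ra] <<- rb
  }
  for (l in links) union2(l[1], l[2])
  # link reciprocally overlapping intervals on the same element
  for (el in unique(elem)) {
    idx <- which(elem == el)
    if (length(idx) < 2) next
    idx <- idx[order(s[idx])]
    for (a in seq_len(length(idx) - 1)) {
      for (b in (a + 1):length(idx)) {
        ia <- idx[a]; ib <- idx[b]
        if (s[ib] >= e[ia]) break
        ov <- min(e[ia], e[ib]) - max(s[ia], s[ib])
        if (ov >= reciprocal * (e[ia] - s[ia]) &&
            ov >= reciprocal * (e[ib] - s[ib]))
          union2(ia, ib)
      }
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  rows <- lapply(split(seq_len(m), roots), function(idx) {
    # representative: highest-scoring interval of the cluster's typical
    # (median) length -- robust against occasional fused/extended intervals
    len <- e[idx] - s[idx]
    med <- stats::median(len)
    typical <- idx[abs(len - med) <= 0.2 * med]
    if (length(typical) == 0) typical <- idx
    rep_i <- typical[which.max(sc[typical])]
    data.frame(self_occurrences = length(unique(elem[idx])),
               rep_element = names(element_seqs)[elem[rep_i]],
               rep_start = s[rep_i], rep_end = e[rep_i],
               score = sc[rep_i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$self_occurrences, -out$score), , drop = FALSE]
  out$unit_id <- sprintf("unit%03d", seq_len(nrow(out)))
  out$seq <- substring(element_seqs[out$rep_element], out$rep_start + 1L,
                       out$rep_end)
  out$length <- nchar(out$seq)
  out <- out[, c("unit_id", "seq", "length", "self_occurrences",
                 "rep_element", "rep_start", "rep_end", "score")]
  rownames(out) <- NULL
  class(out) <- c("candidate_repeats", "data.frame")
  out
}

#' Count merged hits of a unit on target sequences
#'
#' Hits of the unit on each target are merged per target (overlapping hit
#' intervals collapse to one) and the disjoint intervals are counted, so
#' tandem-array staircases are not inflated.
#'
#' @param unit_seq candidate unit sequence
#' @param target_seqs named character vector (e.g. pericentromere sequences)
#' @param min_identity,min_length,scoring alignment thresholds
#' @return integer count of disjoint merged hit intervals
#' @export
count_merged_hits <- function(unit_seq, target_seqs, min_identity = 0.8,
                              min_length = 100L, scoring = align_scoring()) {
  total <- 0L
  for (nm in names(target_seqs)) {
    h <- local_align(unit_seq, target_seqs[[nm]], min_identity = min_identity,
                     min_length = min_length, scoring = scoring)
    if (nrow(h) > 0)
      total <- total + nrow(reduce_intervals(h$tstart, h$tend))
  }
  total
}

#' Occurrence-filter candidate repeats
#'
#' Drops candidates occurring in fewer than `min_self` element records,
#' counts merged hits of the survivors on the pericentromere sequences, and
#' keeps those with strictly more than `min_peri_hits` hits.
#'
#' @param candidates a `candidate_repeats` from [self_cluster()]
#' @param peri_seqs named character vector of pericentromere sequences
#' @param min_self keep clusters with `self_occurrences >= min_self`
#'   (default 50)
#' @param min_peri_hits keep candidates with `peri_hits > min_peri_hits`
#'   (strict; default 1000)
#' @param min_identity,min_length,scoring alignment thresholds for the
#'   pericentromere search
#' @return filtered candidates with a `peri_hits` column
#' @export
filter_candidates <- function(candidates, peri_seqs, min_self = 50L,
                              min_peri_hits = 1000L, min_identity = 0.8,
                              min_length = 100L, scoring = align_scoring()) {
  if (length(peri_seqs) == 0) stop("empty pericentromere set")
  keep <- candidates[candidates$self_occurrences >= min_self, , drop = FALSE]
  keep$peri_hits <- vapply(seq_len(nrow(keep)), function(i)
    count_merged_hits(keep$seq[i], peri_seqs, min_identity, min_length,
                      scoring), integer(1))
  out <- keep[keep$peri_hits > min_peri_hits, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_repeats", "data.frame")
  out
}

#' Flag candidates matching known repeat probes
#'
#' A candidate is flagged `known_overlap` when any local alignment against a
#' known probe reaches `max_identity` over at least `min_length` bp; flagged
#' candidates are excluded from the novel list.
#'
#' @param candidates a `candidate_repeats`
#' @param known_probes named character vector of known repeat monomers
#' @param max_identity identity above which a match counts as known
#'   (default 0.5)
#' @param min_length minimum matching length in bp (default 100)
#' @param scoring an [align_scoring()]; the default tolerates mismatches
#'   (mismatch -1, seed 8) so substitution-diverged similarity down to ~55%
#'   identity is detected, while gaps stay expensive so random sequence
#'   does not produce long gap-riddled pseudo-matches
#' @return candidates with `known_overlap` set; novel ones only
#' @export
filter_known <- function(candidates, known_probes, max_identity = 0.5,
                         min_length = 100L,
                         scoring = align_scoring(mismatch = -1L,
                                                 gap_open = 6L, gap_ext = 3L,
                                                 seed_k = 8L)) {
  flag <- vapply(seq_len(nrow(candidates)), function(i) {
    for (p in seq_along(known_probes)) {
      # a permissive alignment pass, then the known-overlap thresholds
      h <- local_align(candidates$seq[i], known_probes[[p]],
                       min_identity = min(max_identity, 0.5),
                       min_length = min_length, scoring = scoring)
      if (any(h$identity >= max_identity &
              h$aligned_columns >= min_length)) return(TRUE)
    }
    FALSE
  }, logical(1))
  candidates$known_overlap <- flag
  out <- candidates[!flag, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_repeats", "data.frame")
  out
}

#' Collapse candidates contained in longer candidates
#'
#' Clustering can emit a sub-fragment of a unit as its own candidate when
#' partial hits fail the reciprocal-overlap link.  A candidate whose
#' sequence is covered at >= `coverage` of its length by an alignment to a
#' longer candidate (at `min_identity`) is absorbed into it.
#'
#' @param candidates a `candidate_repeats`
#' @param min_identity,coverage containment thresholds (defaults 0.8 / 0.8)
#' @return deduplicated candidates
#' @export
consolidate_candidates <- function(candidates, min_identity = 0.8,
                                   coverage = 0.8) {
  if (nrow(candidates) < 2) return(candidates)
  ord <- order(-candidates$length)
  cand <- candidates[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (j in 2:nrow(cand)) {
    for (i in seq_len(j - 1)) {
      if (!keep[i]) next
      h <- local_align(cand$seq[j], cand$seq[i], min_identity = min_identity,
                       min_length = min(100L, nchar(cand$seq[j])))
      if (nrow(h) > 0 &&
          max(h$aligned_columns) >= coverage * cand$length[j]) {
        keep[j] <- FALSE
        break
      }
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_repeats", "data.frame")
  out
}

#' End-to-end novel-repeat discovery
#'
#' [self_cluster()] on the pericentromere-assigned element sequences,
#' occurrence filtering against the pericentromere sequences, and
#' known-probe exclusion.
#'
#' @param element_seqs named character vector of pericentromeric element
#'   sequences
#' @param peri_seqs named character vector of pericentromere region
#'   sequences
#' @param known_probes named character vector of known satellite monomers
#' @param min_self,min_peri_hits occurrence thresholds (defaults 50 / 1000)
#' @param min_identity,min_length,scoring alignment parameters
#' @return novel `candidate_repeats` (with `peri_hits`, `known_overlap`)
#' @export
discover_repeats <- function(element_seqs, peri_seqs, known_probes = NULL,
                             min_self = 50L, min_peri_hits = 1000L,
                             min_identity = 0.8, min_length = 100L,
                             scoring = align_scoring()) {
  cand <- self_cluster(element_seqs, min_identity = min_identity,
                       min_length = min_length, scoring = scoring)
  cand <- filter_candidates(cand, peri_seqs, min_self = min_self,
                            min_peri_hits = min_peri_hits,
                            min_identity = min_identity,
                            min_length = min_length, scoring = scoring)
  cand <- consolidate_candidates(cand)
  if (!is.null(known_probes) && nrow(cand) > 0)
    cand <- filter_known(cand, known_probes, scoring = scoring)
  else cand$known_overlap <- logical(nrow(cand))
  cand
}

#' Write candidate repeats as FASTA + TSV report
#' @param candidates a `candidate_repeats`
#' @param prefix output path prefix (writes `<prefix>.fa`, `<prefix>.tsv`)
#' @export
write_candidates <- function(candidates, prefix) {
  if (nrow(candidates) > 0)
    write_genome_fasta(setNames(candidates$seq, candidates$unit_id),
                       paste0(prefix, ".fa"))
  cols <- intersect(c("unit_id", "length", "self_occurrences", "peri_hits",
                      "known_overlap", "rep_element", "rep_start", "rep_end"),
                    names(candidates))
  write.table(candidates[, cols], paste0(prefix, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
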
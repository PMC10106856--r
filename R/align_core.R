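#' Alignment scoring parameters
#'
#' Scoring scheme used by the seed-and-extend local aligner and the banded
#' global aligner.  A gap of length L costs `gap_open + (L - 1) * gap_ext`.
#'
#' @param match match score (default +1)
#' @param mismatch mismatch score (default -2)
#' @param gap_open cost of the first gap column (default 3)
#' @param gap_ext cost of each further gap column (default 1)
#' @param seed_k exact-match seed length in bp (default 13)
#' @param diag_join seeds within this many diagonals are chained (default 24)
#' @param gap_join maximum positional gap between chained seeds (default 150)
#' @param window_pad bp added around a seed chain before extension (default 200)
#' @param band_pad extra diagonals allowed around a chain during extension
#'   (default 32)
#' @return a list of class `align_scoring`
#' @export
align_scoring <- function(match = 1L, mismatch = -2L, gap_open = 3L,
                          gap_ext = 1L, seed_k = 13L, diag_join = 24L,
                          gap_join = 150L, window_pad = 200L, band_pad = 32L) {
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open), gap_ext = as.integer(gap_ext),
                 seed_k = as.integer(seed_k), diag_join = as.integer(diag_join),
                 gap_join = as.integer(gap_join),
                 window_pad = as.integer(window_pad),
                 band_pad = as.integer(band_pad)),
            class = "align_scoring")
}

#' Reverse complement of a nucleotide string
#'
#' @param x a character vector of sequences over ACGTN
#' @return reverse-complemented sequences
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

check_seq <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stop("empty ", what)
  invisible(x)
}

#' Seed-and-extend local alignment
#'
#' Finds local alignments of `query` against `target` on both strands using
#' exact k-mer seeds chained by diagonal, followed by banded affine-gap
#' extension.  Overlapping hits of the same query are merged to the
#' highest-scoring.  Hits shorter than `min_length` aligned columns or below
#' `min_identity` (matches / aligned columns) are suppressed.  This
#' (identity, length) threshold pair is the package's analog of a BLAST
#' e-value cutoff; e-value statistics are not computed.
#'
#' Coordinates are 0-based half-open; target coordinates are always on the
#' forward strand, and for minus-strand hits the query interval refers to the
#' forward-strand query.
#'
#' @param query,target nucleotide strings (ACGTN; N never matches)
#' @param min_identity minimum identity fraction (default 0.8)
#' @param min_length minimum aligned columns (default 30)
#' @param scoring an [align_scoring()] list
#' @param both_strands also search the reverse complement of `query`
#'   (default TRUE)
#' @param query_id,target_id labels carried into the hit table
#' @return a data.frame of class `alignment_hits` with columns `query_id`,
#'   `target_id`, `qstart`, `qend`, `tstart`, `tend`, `strand`,
#'   `aligned_columns`, `matches`, `gap_columns`, `identity`, `score`
#' @export
local_align <- function(query, target, min_identity = 0.8, min_length = 30L,
                        scoring = align_scoring(), both_strands = TRUE,
                        query_id = "query", target_id = "target") {
  check_seq(query, "query"); check_seq(target, "target")
  if (min_length < scoring$seed_k)
    stop("min_length must be >= seed length (", scoring$seed_k, ")")
  run1 <- function(q, strand) {
    h <- cpp_local_align(q, target, scoring$seed_k, min_identity,
                         as.integer(min_length), scoring$match,
                         scoring$mismatch, scoring$gap_open, scoring$gap_ext,
                         scoring$diag_join, scoring$gap_join,
                         scoring$window_pad, scoring$band_pad)
    if (nrow(h) == 0L) return(NULL)
    if (strand == "-") {
      qlen <- nchar(q)
      qs <- qlen - h$qend
      h$qend <- qlen - h$qstart
      h$qstart <- qs
    }
    h$strand <- strand
    h
  }
  out <- run1(query, "+")
  if (both_strands) out <- rbind(out, run1(revcomp(query), "-"))
  if (is.null(out) || nrow(out) == 0L) {
    out <- data.frame(qstart = integer(), qend = integer(), tstart = integer(),
                      tend = integer(), matches = integer(),
                      aligned_columns = integer(), gap_columns = integer(),
                      score = integer(), strand = character())
  }
  out$identity <- ifelse(out$aligned_columns > 0,
                         out$matches / out$aligned_columns, 0)
  out <- data.frame(query_id = rep(query_id, nrow(out)),
                    target_id = rep(target_id, nrow(out)),
                    out, stringsAsFactors = FALSE)
  out <- out[order(out$tstart, out$tend), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("alignment_hits", "data.frame")
  out
}

#' Banded global alignment identity
#'
#' Needleman-Wunsch alignment restricted to diagonals within `band` of the
#' main diagonal.  Identity is matches divided by total alignment columns
#' (gap columns count as columns).  `p_obs_gapless` is the mismatch fraction
#' over match/mismatch columns only, the quantity the molecular-clock dating
#' step corrects.
#'
#' @param a,b nucleotide strings
#' @param band maximum diagonal offset in bp; the band must cover the length
#'   difference or the alignment is infeasible
#' @param scoring an [align_scoring()] list
#' @return list with `identity`, `aligned_columns`, `matches`,
#'   `gap_columns`, `p_obs_gapless`, `score`
#' @export
global_identity <- function(a, b, band = NULL, scoring = align_scoring()) {
  check_seq(a, "sequence a"); check_seq(b, "sequence b")
  if (is.null(band)) band <- max(32L, ceiling(0.1 * max(nchar(a), nchar(b))))
  r <- cpp_banded_global(a, b, as.integer(band), scoring$match,
                         scoring$mismatch, scoring$gap_open, scoring$gap_ext)
  if (!isTRUE(r$feasible))
    stop("infeasible-band: band ", band,
         " cannot connect alignment corners for lengths ",
         nchar(a), " and ", nchar(b))
  mm_cols <- r$columns - r$gap_columns
  list(identity = r$matches / r$columns,
       aligned_columns = r$columns,
       matches = r$matches,
       gap_columns = r$gap_columns,
       p_obs_gapless = if (mm_cols > 0) (mm_cols - r$matches) / mm_cols else 0,
       score = r$score)
}

#' Jukes-Cantor (JC69) distance correction
#'
#' Converts an observed mismatch fraction into substitutions per site:
#' K = -(3/4) ln(1 - (4/3) p).  Defined for p < 0.75; larger values are
#' saturated and rejected.
#'
#' @param p_obs observed mismatch fraction(s) in `[0, 0.75)`
#' @return substitutions per site, same length as `p_obs`
#' @export
jc69_distance <- function(p_obs) {
  if (any(p_obs < 0, na.rm = TRUE)) stop("p_obs must be nonnegative")
  if (any(p_obs >= 0.75, na.rm = TRUE))
    stop("saturation: JC69 undefined for p_obs >= 0.75")
  -0.75 * log(1 - (4 / 3) * p_obs)
}

#' Kimura two-parameter (K2P) distance
#'
#' K = -(1/2) ln(1 - 2p - q) - (1/4) ln(1 - 2q) for transition fraction p and
#' transversion fraction q.
#'
#' @param p_transitions observed transition fraction
#' @param q_transversions observed transversion fraction
#' @return substitutions per site
#' @export
k2p_distance <- function(p_transitions, q_transversions) {
  if (any(p_transitions < 0) || any(q_transversions < 0))
    stop("fractions must be nonnegative")
  a <- 1 - 2 * p_transitions - q_transversions
  b <- 1 - 2 * q_transversions
  if (any(a <= 0) || any(b <= 0))
    stop("saturation: K2P log-domain violation")
  -0.5 * log(a) - 0.25 * log(b)
}

#' Fast k-mer containment identity estimate
#'
#' Distinct-k-mer containment raised to 1/k; a cheap stand-in for alignment
#' identity, always labelled an estimate.
#'
#' @param a,b nucleotide strings
#' @param k k-mer length (default 13)
#' @return estimated identity fraction
#' @export
kmer_identity <- function(a, b, k = 13L) {
  check_seq(a, "sequence a"); check_seq(b, "sequence b")
  cpp_kmer_identity(a, b, as.integer(k))
}

#' Write alignment hits as a BLAST-outfmt6-like TSV
#'
#' Columns: query, target, percent identity, alignment length, mismatches,
#' gap columns, qstart, qend, tstart, tend, strand, score (intervals 0-based
#' half-open, matching the in-memory representation).
#'
#' @param hits an `alignment_hits` data.frame from [local_align()]
#' @param path output file
#' @export
write_hits_tsv <- function(hits, path) {
  out <- data.frame(query = hits$query_id, target = hits$target_id,
                    pident = round(100 * hits$identity, 2),
                    length = hits$aligned_columns,
                    mismatches = hits$aligned_columns - hits$gap_columns - hits$matches,
                    gaps = hits$gap_columns,
                    qstart = hits$qstart, qend = hits$qend,
                    tstart = hits$tstart, tend = hits$tend,
                    strand = hits$strand, score = hits$score)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, and optionally
#'   `name` and `score`
#' @param path output file
#' @export
write_bed <- function(df, path) {
  bed <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    name = if ("name" %in% names(df)) df$name else ".",
                    score = if ("score" %in% names(df)) df$score else 0)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
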
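# Satellite probe mapping, sliding-window density tracks and telomere
# screening.

#' Build a probe set
#'
#' @param centromeric,pericentromeric,telomeric named character vectors of
#'   monomer sequences per role (names become probe ids)
#' @return data.frame with `id`, `role`, `seq`
#' @export
probe_set <- function(centromeric = character(), pericentromeric = character(),
                      telomeric = character()) {
  mk <- function(x, role) {
    if (length(x) == 0) return(NULL)
    if (is.null(names(x)) || any(names(x) == ""))
      names(x) <- paste0(substr(role, 1, 4), "_", seq_along(x))
    data.frame(id = names(x), role = role, seq = unname(x),
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk(centromeric, "centromeric"),
               mk(pericentromeric, "pericentromeric"),
               mk(telomeric, "telomeric"))
  if (is.null(out) || nrow(out) == 0) stop("probes non-empty required")
  if (anyDuplicated(out$id)) stop("probe ids must be unique")
  bad <- setdiff(out$role, c("centromeric", "pericentromeric", "telomeric"))
  if (length(bad)) stop("unknown probe role: ", paste(bad, collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Map repeat-probe monomers onto a genome
#'
#' Local alignment of every monomer against every chromosome on both
#' strands; hits carry the probe's role.  The default minimum hit length is
#' half the monomer length (fragmented satellite copies still count), and
#' the seed length is lowered to 11 so diverged copies near the identity
#' threshold are still seeded.
#'
#' @param genome named character vector of chromosome sequences
#' @param probes a [probe_set()] data.frame
#' @param min_identity minimum identity fraction (default 0.8)
#' @param min_length minimum aligned columns; default half the monomer
#' @param scoring an [align_scoring()]; default uses `seed_k = 11`
#' @return `alignment_hits` data.frame with a `role` column; `target_id` is
#'   the chromosome
#' @export
map_probes <- function(genome, probes, min_identity = 0.8, min_length = NULL,
                       scoring = align_scoring(seed_k = 11L)) {
  if (nrow(probes) == 0) stop("probes non-empty required")
  out <- list()
  for (chrom in names(genome)) {
    for (i in seq_len(nrow(probes))) {
      ml <- if (is.null(min_length))
        max(scoring$seed_k, floor(nchar(probes$seq[i]) / 2)) else min_length
      h <- local_align(probes$seq[i], genome[[chrom]],
                       min_identity = min_identity, min_length = ml,
                       scoring = scoring, query_id = probes$id[i],
                       target_id = chrom)
      if (nrow(h) > 0) {
        h$role <- probes$role[i]
        out[[length(out) + 1L]] <- h
      }
    }
  }
  if (length(out) == 0) {
    h <- local_align("ACGTACGTACGTACGT", "ACGTACGTACGTACGT",
                     min_length = 16)[0, ]
    h$role <- character(0)
    return(h)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("alignment_hits", "data.frame")
  res
}

# union of [start,end) intervals as an IRanges (0-based halfopen -> shifted)
reduce_intervals <- function(start, end) {
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  data.frame(start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir))
}

#' Sliding-window covered-bp density track
#'
#' Per window, the fraction of bases covered by the union of the role's
#' probe hits.  Windows tile `[0, chrom_length)` with the given step; the
#' last partial window is normalised by its actual width.  Densities are
#' covered-bp fractions, not hit counts, so tandem-array fragmentation and
#' overlapping hits do not inflate the signal.
#'
#' @param hits `alignment_hits` on one chromosome (from [map_probes()])
#' @param chrom_length chromosome length in bp
#' @param window_size window in bp (default 500000)
#' @param step step in bp (default 100000)
#' @param role optional role filter (uses `hits$role`)
#' @return a `window_track` data.frame: `chrom`, `start`, `end`, `value`,
#'   with attributes `window_size`, `step`, `role`
#' @export
density_track <- function(hits, chrom_length, window_size = 5e5, step = 1e5,
                          role = NULL) {
  if (step > window_size) stop("step must not exceed window_size")
  if (!is.null(role)) hits <- hits[hits$role == role, , drop = FALSE]
  chrom <- if (nrow(hits) > 0) hits$target_id[1] else "chr"
  if (nrow(hits) > 0 && length(unique(hits$target_id)) > 1)
    stop("hits must be on one chromosome")
  starts <- seq(0L, max(0L, chrom_length - 1L), by = step)
  ends <- pmin(starts + window_size, chrom_length)
  cov <- numeric(length(starts))
  if (nrow(hits) > 0) {
    red <- reduce_intervals(hits$tstart, hits$tend)
    cv <- IRanges::coverage(IRanges::IRanges(red$start + 1L, red$end),
                            width = chrom_length)
    csum <- c(0, cumsum(S4Vectors::runValue(cv) * S4Vectors::runLength(cv)))
    bounds <- c(0, cumsum(S4Vectors::runLength(cv)))
    covered_upto <- function(pos) { # covered bases in [0, pos)
      i <- findInterval(pos, bounds, left.open = TRUE)
      i[i < 1L] <- 1L
      csum[i] + S4Vectors::runValue(cv)[i] * (pos - bounds[i])
    }
    cov <- covered_upto(ends) - covered_upto(starts)
  }
  track <- data.frame(chrom = chrom, start = starts, end = ends,
                      value = cov / (ends - starts))
  attr(track, "window_size") <- window_size
  attr(track, "step") <- step
  attr(track, "role") <- role
  class(track) <- c("window_track", "data.frame")
  track
}

#' Write a density track as bedGraph
#' @param track a `window_track`
#' @param path output file
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- sprintf("track type=bedGraph name=%s window=%s step=%s",
                  attr(track, "role") %||% "density",
                  attr(track, "window_size"), attr(track, "step"))
  writeLines(meta, con)
  write.table(track[, c("chrom", "start", "end", "value")], con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen chromosome ends for telomere arrays
#'
#' An end is flagged telomeric when the fraction of its terminal window
#' covered by exact matches of the telomere motif (either strand) reaches
#' `min_fraction`.  Chromosomes shorter than `end_window` are evaluated over
#' their full length.
#'
#' @param genome named character vector of chromosome sequences
#' @param telomere_motif motif (length >= 5)
#' @param end_window terminal window in bp (default 10000)
#' @param min_fraction coverage fraction required (default 0.2)
#' @return data.frame: `chrom`, `end` (left/right), `coverage`, `telomeric`
#' @export
detect_telomeres <- function(genome, telomere_motif, end_window = 1e4,
                             min_fraction = 0.2) {
  if (nchar(telomere_motif) < 5) stop("motif length >= 5 required")
  pats <- Biostrings::DNAStringSet(c(telomere_motif, revcomp(telomere_motif)))
  rows <- list()
  for (chrom in names(genome)) {
    s <- Biostrings::DNAString(genome[[chrom]])
    n <- length(s)
    w <- min(end_window, n)
    for (side in c("left", "right")) {
      sub <- if (side == "left") s[seq_len(w)] else s[(n - w + 1):n]
      cov <- S4Vectors::Rle(0L, w)
      for (p in seq_along(pats)) {
        m <- Biostrings::matchPattern(pats[[p]], sub)
        if (length(m) > 0) {
          ir <- IRanges::IRanges(start = BiocGenerics::start(m),
                                 end = BiocGenerics::end(m))
          cov <- cov | IRanges::coverage(ir, width = w)
        }
      }
      frac <- sum(as.integer(cov)) / w
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = chrom, end = side, coverage = frac,
                   telomeric = frac >= min_fraction)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
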
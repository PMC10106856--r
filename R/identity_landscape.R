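# Pairwise sequence-identity matrices over non-overlapping bins of a
# region, and a minimal change-point segmentation of the resulting block
# structure.

#' Pairwise identity matrix over non-overlapping bins
#'
#' Cuts the region into consecutive `bin_size` bins (the trailing partial
#' bin is dropped), and computes identity for every bin pair: banded global
#' alignment identity (gap columns count as columns) by default, or the
#' k-mer containment estimate (`method = "kmer"`, labelled an estimate).
#' Bins are compared on the forward strand.
#'
#' @param region_seq nucleotide string (length >= 2 * bin_size)
#' @param bin_size bin width in bp (default 10000)
#' @param method "global" (alignment, default) or "kmer" (fast estimate)
#' @param band_frac band width for the global method, as a fraction of
#'   `bin_size` (default 0.1)
#' @return an `identity_matrix` list: `matrix` (symmetric, unit diagonal),
#'   `bins` (data.frame of 0-based half-open bin coordinates), `bin_size`,
#'   `method`
#' @export
identity_matrix <- function(region_seq, bin_size = 1e4,
                            method = c("global", "kmer"), band_frac = 0.1) {
  method <- match.arg(method)
  check_seq(region_seq, "region")
  n_bins <- floor(nchar(region_seq) / bin_size)
  if (n_bins < 2) stop("region must span at least two bins")
  bins <- data.frame(start = (seq_len(n_bins) - 1L) * bin_size)
  bins$end <- bins$start + bin_size
  seqs <- substring(region_seq, bins$start + 1L, bins$end)
  M <- diag(1, n_bins)
  band <- max(32L, ceiling(band_frac * bin_size))
  for (i in seq_len(n_bins - 1)) {
    for (j in (i + 1):n_bins) {
      v <- if (method == "global")
        global_identity(seqs[i], seqs[j], band = band)$identity
      else cpp_kmer_identity(seqs[i], seqs[j], 13L)
      M[i, j] <- M[j, i] <- v
    }
  }
  structure(list(matrix = M, bins = bins, bin_size = bin_size,
                 method = method), class = "identity_matrix")
}

# mean of off-diagonal entries of a submatrix (NA when empty)
block_mean <- function(M, rows, cols) {
  v <- M[rows, cols, drop = FALSE]
  if (identical(rows, cols)) {
    if (length(rows) < 2) return(NA_real_)
    mean(v[upper.tri(v)])
  } else mean(v)
}

#' Segment an identity matrix into homogeneous blocks
#'
#' Recursive binary change-point splitting: a segment is split at the
#' boundary maximising the gap between mean within-block identity and mean
#' between-block identity; the split is accepted when the gap exceeds
#' `cut`.  An interpretive aid for labelling block structure, not a full
#' segmentation model.
#'
#' @param im an [identity_matrix()] (or a plain symmetric matrix)
#' @param cut minimum within-minus-between identity gap to accept a split
#'   (default 0.1)
#' @param min_bins smallest block size in bins (default 2)
#' @return data.frame of bin-index intervals `first`, `last` (1-based,
#'   inclusive) and bp coordinates when bins are available
#' @export
segment_blocks <- function(im, cut = 0.1, min_bins = 2L) {
  M <- if (inherits(im, "identity_matrix")) im$matrix else im
  n <- nrow(M)
  segs <- list()
  split_rec <- function(first, last) {
    len <- last - first + 1L
    if (len < 2L * min_bins) {
      segs[[length(segs) + 1L]] <<- c(first, last)
      return(invisible())
    }
    best_gap <- -Inf; best_b <- NA_integer_
    for (b in (first + min_bins - 1L):(last - min_bins)) {
      left <- first:b; right <- (b + 1L):last
      wl <- block_mean(M, left, left)
      wr <- block_mean(M, right, right)
      btw <- block_mean(M, left, right)
      gap <- mean(c(wl, wr), na.rm = TRUE) - btw
      if (!is.na(gap) && gap > best_gap) { best_gap <- gap; best_b <- b }
    }
    if (!is.na(best_b) && best_gap >= cut) {
      split_rec(first, best_b)
      split_rec(best_b + 1L, last)
    } else {
      segs[[length(segs) + 1L]] <<- c(first, last)
    }
    invisible()
  }
  split_rec(1L, n)
  out <- as.data.frame(do.call(rbind, segs))
  names(out) <- c("first", "last")
  out <- out[order(out$first), , drop = FALSE]
  if (inherits(im, "identity_matrix")) {
    out$start <- im$bins$start[out$first]
    out$end <- im$bins$end[out$last]
  }
  rownames(out) <- NULL
  out
}

#' Write an identity matrix as TSV (bin coordinates + values)
#' @param im an [identity_matrix()]
#' @param path output file
#' @export
write_identity_tsv <- function(im, path) {
  lab <- sprintf("%d-%d", im$bins$start, im$bins$end)
  m <- im$matrix
  dimnames(m) <- list(lab, lab)
  write.table(round(m, 4), path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Plot an identity matrix heatmap
#'
#' Uses pheatmap when installed, else base `image()`.
#'
#' @param im an [identity_matrix()]
#' @param path optional PNG output path
#' @export
plot_identity_matrix <- function(im, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 800, height = 800)
    on.exit(grDevices::dev.off())
  }
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(im$matrix, cluster_rows = FALSE, cluster_cols = FALSE,
                       main = sprintf("pairwise identity, %d bp bins",
                                      im$bin_size))
  } else {
    graphics::image(im$matrix, main = sprintf("pairwise identity, %d bp bins",
                                              im$bin_size))
  }
  invisible(im)
}
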
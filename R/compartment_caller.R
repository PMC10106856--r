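# Convert role-specific density tracks into centromere / pericentromere
# interval calls.  The boundary criterion (threshold, minimum run, merge
# gap) is explicit and stamped into every call.

#' Call enriched regions from a density track
#'
#' Windows with density >= `threshold` form runs; runs separated by at most
#' `merge_gap` below-threshold windows are merged; merged runs shorter than
#' `min_run` windows are dropped.  When probe hits are supplied, each
#' region's boundaries are snapped to the outermost hit endpoints inside the
#' merged run (not window-rounded).
#'
#' @param track a `window_track` from [density_track()]
#' @param threshold density threshold (default 0.1)
#' @param min_run minimum run length in windows (default 2)
#' @param merge_gap maximum below-threshold gap merged, in windows
#'   (default 2)
#' @param hits optional `alignment_hits` used for boundary snapping
#' @param role role label stored on the calls (default from track)
#' @return a `region_annotation` data.frame: `chrom`, `start`, `end`,
#'   `role`, `evidence` (mean in-region window density), with the caller
#'   parameters as an attribute
#' @export
call_regions <- function(track, threshold = 0.1, min_run = 2L,
                         merge_gap = 2L, hits = NULL, role = NULL) {
  if (nrow(track) == 0) stop("empty track")
  if (is.unsorted(track$start)) track <- track[order(track$start), ]
  role <- role %||% attr(track, "role") %||% "region"
  above <- track$value >= threshold
  regions <- list()
  if (any(above)) {
    r <- rle(above)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    runs <- data.frame(start = idx_start[r$values], end = idx_end[r$values])
    # merge runs separated by <= merge_gap below-threshold windows
    if (nrow(runs) > 1) {
      keep <- runs[1, , drop = FALSE]
      for (i in 2:nrow(runs)) {
        gap <- runs$start[i] - keep$end[nrow(keep)] - 1L
        if (gap <= merge_gap) keep$end[nrow(keep)] <- runs$end[i]
        else keep <- rbind(keep, runs[i, ])
      }
      runs <- keep
    }
    # window runs overlap (window > step): a run's bp extent is from the
    # first window's start to the last window's end
    runs$len <- runs$end - runs$start + 1L
    runs <- runs[runs$len >= min_run, , drop = FALSE]
    for (i in seq_len(nrow(runs))) {
      s_bp <- track$start[runs$start[i]]
      e_bp <- track$end[runs$end[i]]
      s <- s_bp; e <- e_bp
      if (!is.null(hits) && nrow(hits) > 0) {
        inside <- hits$tstart < e_bp & hits$tend > s_bp
        if (any(inside)) {
          s <- min(hits$tstart[inside])
          e <- max(hits$tend[inside])
          s <- max(s, 0L)
        }
      }
      ev <- mean(track$value[runs$start[i]:runs$end[i]])
      regions[[length(regions) + 1L]] <-
        data.frame(chrom = track$chrom[1], start = s, end = e, role = role,
                   evidence = ev, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               role = character(), evidence = numeric())
  rownames(out) <- NULL
  attr(out, "params") <- list(threshold = threshold, min_run = min_run,
                              merge_gap = merge_gap,
                              window_size = attr(track, "window_size"),
                              step = attr(track, "step"))
  class(out) <- c("region_annotation", "data.frame")
  out
}

#' Call centromere and pericentromere compartments for one chromosome
#'
#' Centromeres are called from the centromeric-probe track; pericentromeres
#' from the pericentromeric-probe track, and only the portions flanking (not
#' inside) the centromere call are kept.
#'
#' @param hits `alignment_hits` from [map_probes()] for one chromosome
#' @param chrom_length chromosome length in bp
#' @param window_size,step sliding-window parameters in bp
#' @param threshold,min_run,merge_gap see [call_regions()]
#' @return a `region_annotation` data.frame with roles `centromere` and
#'   `pericentromere`
#' @export
call_compartments <- function(hits, chrom_length, window_size = 5e5,
                              step = 1e5, threshold = 0.1, min_run = 2L,
                              merge_gap = 2L) {
  cent_hits <- hits[hits$role == "centromeric", , drop = FALSE]
  peri_hits <- hits[hits$role == "pericentromeric", , drop = FALSE]
  cent_track <- density_track(cent_hits, chrom_length, window_size, step,
                              role = NULL)
  peri_track <- density_track(peri_hits, chrom_length, window_size, step,
                              role = NULL)
  cent <- call_regions(cent_track, threshold, min_run, merge_gap,
                       hits = cent_hits, role = "centromere")
  peri <- call_regions(peri_track, threshold, min_run, merge_gap,
                       hits = peri_hits, role = "pericentromere")
  # pericentromeres flank the centromere: subtract centromere intervals
  if (nrow(peri) > 0 && nrow(cent) > 0) {
    pir <- IRanges::IRanges(peri$start + 1L, peri$end)
    cir <- IRanges::reduce(IRanges::IRanges(cent$start + 1L, cent$end))
    kept <- BiocGenerics::setdiff(pir, cir)
    peri <- data.frame(chrom = cent$chrom[1],
                       start = BiocGenerics::start(kept) - 1L,
                       end = BiocGenerics::end(kept),
                       role = "pericentromere",
                       evidence = rep(mean(peri$evidence), length(kept)),
                       stringsAsFactors = FALSE)
  }
  out <- rbind(as.data.frame(cent), as.data.frame(peri))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "params") <- attr(cent, "params")
  class(out) <- c("region_annotation", "data.frame")
  out
}

#' Assign items to compartments by the midpoint rule
#'
#' Each item is labelled by the role of the called region containing its
#' midpoint; centromere takes precedence over pericentromere on overlap;
#' items whose midpoint falls in no region are `non-(peri)centromere`.
#'
#' @param items data.frame with `start`, `end` (0-based half-open) and
#'   optionally `chrom`
#' @param regions a `region_annotation` (roles centromere / pericentromere)
#' @param chrom_length optional bound check
#' @return character vector of compartment labels
#' @export
assign_compartments <- function(items, regions, chrom_length = NULL) {
  if (nrow(items) == 0) return(character(0))
  if (!is.null(chrom_length) &&
      any(items$start < 0 | items$end > chrom_length))
    stop("item outside chromosome bounds")
  mid <- floor((items$start + items$end) / 2)
  lab <- rep("non-(peri)centromere", nrow(items))
  for (rl in c("pericentromere", "centromere")) { # centromere last: precedence
    rg <- regions[regions$role == rl, , drop = FALSE]
    for (i in seq_len(nrow(rg))) {
      hit <- mid >= rg$start[i] & mid < rg$end[i]
      if ("chrom" %in% names(items) && "chrom" %in% names(rg))
        hit <- hit & items$chrom == rg$chrom[i]
      lab[hit] <- rl
    }
  }
  lab
}

#' Write region calls as BED with a JSON parameter sidecar
#' @param regions a `region_annotation`
#' @param path BED output path; the sidecar is `<path>.params.json`
#' @export
write_regions_bed <- function(regions, path) {
  write_bed(data.frame(chrom = regions$chrom, start = regions$start,
                       end = regions$end, name = regions$role,
                       score = round(1000 * regions$evidence)), path)
  p <- attr(regions, "params")
  if (!is.null(p))
    jsonlite::write_json(p, paste0(path, ".params.json"), auto_unbox = TRUE)
  invisible(path)
}
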
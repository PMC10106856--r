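# Compartment-level statistics, age contrasts, and the end-to-end pipeline
# driver.

#' Fraction of a region set covered by features
#'
#' Overlapping feature intervals are merged, intersected with the (merged)
#' regions; the fraction is covered bp / region bp.
#'
#' @param regions data.frame with `start`, `end` (0-based half-open; one
#'   coordinate system, e.g. one chromosome)
#' @param features data.frame with `start`, `end` on the same system
#' @return covered fraction in `[0, 1]`
#' @export
coverage_fraction <- function(regions, features) {
  if (nrow(regions) == 0) stop("empty regions")
  rr <- IRanges::reduce(IRanges::IRanges(regions$start + 1L, regions$end))
  region_bp <- sum(BiocGenerics::width(rr))
  if (region_bp == 0) stop("empty regions")
  if (nrow(features) == 0) return(0)
  fr <- IRanges::reduce(IRanges::IRanges(features$start + 1L, features$end))
  ov <- BiocGenerics::intersect(rr, fr)
  sum(BiocGenerics::width(ov)) / region_bp
}

#' Welch two-sample age contrast
#'
#' Welch (unequal-variance) t statistic with two-sided p, plus group means.
#' With zero variance in both groups and equal means, t = 0 and p = 1 by
#' convention.  A pooled-variance test is available via `pooled = TRUE`.
#'
#' @param ages_a,ages_b numeric vectors (each n >= 2, finite)
#' @param pooled use the pooled-variance t-test instead of Welch
#' @return list: `t`, `p`, `mean_a`, `mean_b`, `n_a`, `n_b`, `df`
#' @export
age_contrast <- function(ages_a, ages_b, pooled = FALSE) {
  if (length(ages_a) < 2 || length(ages_b) < 2)
    stop("each group needs n >= 2")
  if (!all(is.finite(ages_a)) || !all(is.finite(ages_b)))
    stop("ages must be finite")
  if (sd(ages_a) == 0 && sd(ages_b) == 0) {
    eq <- mean(ages_a) == mean(ages_b)
    return(list(t = if (eq) 0 else Inf * sign(mean(ages_a) - mean(ages_b)),
                p = if (eq) 1 else 0,
                mean_a = mean(ages_a), mean_b = mean(ages_b),
                n_a = length(ages_a), n_b = length(ages_b), df = NA_real_))
  }
  ht <- t.test(ages_a, ages_b, var.equal = pooled)
  list(t = unname(ht$statistic), p = ht$p.value,
       mean_a = mean(ages_a), mean_b = mean(ages_b),
       n_a = length(ages_a), n_b = length(ages_b),
       df = unname(ht$parameter))
}

#' Summarise dated elements per compartment
#'
#' @param elements dated `ltr_elements` with a `compartment` column
#' @param regions called `region_annotation` (for satellite/TE coverage,
#'   optional)
#' @param hits optional probe `alignment_hits` for satellite coverage
#' @param young_threshold MYA boundary (default 0.5)
#' @return data.frame per compartment: n, mean/median age, young fraction,
#'   Copia and Gypsy percent
#' @export
compartment_stats <- function(elements, regions = NULL, hits = NULL,
                              young_threshold = 0.5) {
  el <- elements[!is.na(elements$age_mya) & elements$reliable, , drop = FALSE]
  rows <- lapply(split(el, el$compartment), function(d) {
    data.frame(compartment = d$compartment[1],
               n = nrow(d),
               mean_age_mya = mean(d$age_mya),
               median_age_mya = stats::median(d$age_mya),
               young_fraction = mean(d$age_mya <= young_threshold),
               copia_pct = 100 * mean(d$superfamily == "Copia"),
               gypsy_pct = 100 * mean(d$superfamily == "Gypsy"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(regions) && !is.null(hits)) {
    sat <- vapply(out$compartment, function(cp) {
      rg <- regions[regions$role == cp, , drop = FALSE]
      if (nrow(rg) == 0) return(NA_real_)
      coverage_fraction(rg, data.frame(start = hits$tstart, end = hits$tend))
    }, numeric(1))
    out$satellite_covered <- sat
  }
  if (!is.null(regions)) {
    te <- vapply(out$compartment, function(cp) {
      rg <- regions[regions$role == cp, , drop = FALSE]
      if (nrow(rg) == 0) return(NA_real_)
      ecp <- elements[elements$compartment == cp, , drop = FALSE]
      if (nrow(ecp) == 0) return(0)
      coverage_fraction(rg, data.frame(start = ecp$start, end = ecp$end))
    }, numeric(1))
    out$ltr_covered <- te
  }
  rownames(out) <- NULL
  out
}

#' Run the full landscape pipeline on a genome
#'
#' Probe mapping, density tracks, compartment calls, LTR dating (from a
#' GFF3 annotation when given, else the simplified structural finder),
#' nested-insertion detection, compartment statistics and contrasts,
#' identity matrix of each called centromere, and novel-repeat discovery.
#' All outputs plus a parameter snapshot are written under `out_dir`.
#'
#' @param genome named character vector, or a FASTA path
#' @param probes a [probe_set()] data.frame, or a truth `probes` table
#' @param out_dir output directory
#' @param ltr_gff3 optional GFF3 annotation of full-length LTR elements
#' @param window_size,step,threshold,min_run,merge_gap compartment-calling
#'   parameters
#' @param mu,model dating parameters
#' @param min_self,min_peri_hits discovery thresholds
#' @param bin_size identity-matrix bin width (bp)
#' @param seed integer seed recorded in the snapshot
#' @param verbose print stage progress
#' @return invisibly, a list with all result tables
#' @export
run_pipeline <- function(genome, probes, out_dir, ltr_gff3 = NULL,
                         window_size = 5e5, step = 1e5, threshold = 0.1,
                         min_run = 2L, merge_gap = 2L, mu = 1.5e-8,
                         model = "JC69", min_self = 50L,
                         min_peri_hits = 1000L, bin_size = 1e4,
                         seed = 1L, verbose = TRUE) {
  say <- function(...) if (verbose) message("[centroscape] ", ...)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- read_genome_fasta(genome)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say("mapping ", nrow(probes), " probes on ", length(genome), " sequence(s)")
  hits <- map_probes(genome, probes)
  write_hits_tsv(hits, file.path(out_dir, "probe_hits.tsv"))
  tel <- detect_telomeres(genome, probes$seq[probes$role == "telomeric"][1])
  write.table(tel, file.path(out_dir, "telomeres.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  regions_all <- list(); tracks <- list()
  for (chrom in names(genome)) {
    ch <- hits[hits$target_id == chrom, , drop = FALSE]
    clen <- nchar(genome[[chrom]])
    for (role in c("centromeric", "pericentromeric")) {
      tr <- density_track(ch[ch$role == role, , drop = FALSE], clen,
                          window_size, step, role = NULL)
      attr(tr, "role") <- role
      tracks[[paste(chrom, role)]] <- tr
      write_bedgraph(tr, file.path(out_dir, paste0(chrom, ".", role,
                                                   ".bedgraph")))
    }
    regions_all[[chrom]] <- call_compartments(ch, clen, window_size, step,
                                              threshold, min_run, merge_gap)
  }
  regions <- do.call(rbind, lapply(regions_all, as.data.frame))
  rownames(regions) <- NULL
  attr(regions, "params") <- attr(regions_all[[1]], "params")
  class(regions) <- c("region_annotation", "data.frame")
  write_regions_bed(regions, file.path(out_dir, "regions.bed"))
  say("called ", sum(regions$role == "centromere"), " centromere and ",
      sum(regions$role == "pericentromere"), " pericentromere region(s)")
  # elements
  if (!is.null(ltr_gff3)) {
    elements <- read_ltr_annotations(ltr_gff3, genome)
  } else {
    say("no LTR annotation given: using the simplified structural finder")
    elements <- find_ltr_elements(genome)
  }
  stats <- NULL; contrasts <- NULL; nested <- NULL
  if (nrow(elements) > 0) {
    elements <- estimate_age(elements, genome, mu = mu, model = model)
    elements$compartment <- assign_compartments(elements, regions)
    write.table(elements, file.path(out_dir, "elements_dated.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    nested <- detect_nested(elements)
    write.table(nested, file.path(out_dir, "nested_insertions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    stats <- compartment_stats(elements, regions, hits)
    write.table(stats, file.path(out_dir, "compartment_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    grp <- split(elements$age_mya[elements$reliable],
                 elements$compartment[elements$reliable])
    pairs <- utils::combn(names(grp), 2, simplify = FALSE)
    contrasts <- do.call(rbind, lapply(pairs, function(p) {
      if (length(grp[[p[1]]]) < 2 || length(grp[[p[2]]]) < 2) return(NULL)
      ct <- age_contrast(grp[[p[1]]], grp[[p[2]]])
      data.frame(group_a = p[1], group_b = p[2], t = ct$t, p = ct$p,
                 mean_a = ct$mean_a, mean_b = ct$mean_b, n_a = ct$n_a,
                 n_b = ct$n_b)
    }))
    if (!is.null(contrasts))
      write.table(contrasts, file.path(out_dir, "age_contrasts.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  # identity matrix per called centromere
  cents <- regions[regions$role == "centromere", , drop = FALSE]
  for (i in seq_len(nrow(cents))) {
    sub <- substr(genome[[cents$chrom[i]]], cents$start[i] + 1L, cents$end[i])
    if (nchar(sub) >= 2 * bin_size) {
      im <- identity_matrix(sub, bin_size = bin_size)
      write_identity_tsv(im, file.path(out_dir,
                                       sprintf("%s_cent%d_identity.tsv",
                                               cents$chrom[i], i)))
    }
  }
  # novel-repeat discovery on pericentromeric elements
  novel <- NULL
  if (!is.null(elements) && nrow(elements) > 0) {
    peri_el <- elements[elements$compartment == "pericentromere", ,
                        drop = FALSE]
    peri_rg <- regions[regions$role == "pericentromere", , drop = FALSE]
    if (nrow(peri_el) >= 2 && nrow(peri_rg) > 0) {
      el_seqs <- vapply(seq_len(nrow(peri_el)), function(i)
        substr(genome[[peri_el$chrom[i]]], peri_el$start[i] + 1L,
               peri_el$end[i]), character(1))
      names(el_seqs) <- peri_el$id
      peri_seqs <- vapply(seq_len(nrow(peri_rg)), function(i)
        substr(genome[[peri_rg$chrom[i]]], peri_rg$start[i] + 1L,
               peri_rg$end[i]), character(1))
      names(peri_seqs) <- sprintf("peri%d", seq_len(nrow(peri_rg)))
      known <- setNames(probes$seq[probes$role == "pericentromeric"],
                        probes$id[probes$role == "pericentromeric"])
      novel <- discover_repeats(el_seqs, peri_seqs, known,
                                min_self = min_self,
                                min_peri_hits = min_peri_hits)
      write_candidates(novel, file.path(out_dir, "novel_repeats"))
      say("novel repeat candidates: ", nrow(novel))
    }
  }
  snapshot <- list(window_size = window_size, step = step,
                   threshold = threshold, min_run = min_run,
                   merge_gap = merge_gap, mu = mu, model = model,
                   min_self = min_self, min_peri_hits = min_peri_hits,
                   bin_size = bin_size, seed = seed,
                   annotation = if (is.null(ltr_gff3)) "structural-finder"
                                else ltr_gff3)
  jsonlite::write_json(snapshot, file.path(out_dir, "params.json"),
                       auto_unbox = TRUE)
  invisible(list(hits = hits, telomeres = tel, tracks = tracks,
                 regions = regions, elements = elements, nested = nested,
                 stats = stats, contrasts = contrasts, novel = novel,
                 params = snapshot))
}
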
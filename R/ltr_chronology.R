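# Full-length LTR retrotransposon dating, young/old classification, nested
# insertion detection and compartment composition tables.
#
# Insertion age T = K / (2 mu): the two LTR copies of an element are
# identical at insertion and diverge independently, so their pairwise
# model-corrected distance K accumulates at 2 mu per year.

#' Read full-length LTR element annotations from GFF3
#'
#' Expects element records (type containing "retrotransposon" or
#' "repeat_region") with two `long_terminal_repeat` sub-features linked by
#' `Parent`.  GFF3 1-based inclusive coordinates are converted to the
#' package's 0-based half-open convention.  Elements lacking two LTR
#' sub-features are skipped with a warning; the skip count is reported as an
#' attribute.
#'
#' @param path GFF3 file
#' @param genome optional named character vector for bounds checking
#' @return `ltr_elements` data.frame: `id`, `chrom`, `start`, `end`,
#'   `ltr5_start`, `ltr5_end`, `ltr3_start`, `ltr3_end`, `family`,
#'   `superfamily`
#' @export
read_ltr_annotations <- function(path, genome = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) stop("empty GFF3")
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(f, length, integer(1)) < 9
  f <- f[!bad]
  gff <- data.frame(chrom = vapply(f, `[`, "", 1),
                    type = vapply(f, `[`, "", 3),
                    start = as.integer(vapply(f, `[`, "", 4)),
                    end = as.integer(vapply(f, `[`, "", 5)),
                    attrs = vapply(f, `[`, "", 9),
                    stringsAsFactors = FALSE)
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(^|;)", key, "=([^;]*)"), attrs))
    vapply(m, function(x) if (length(x) >= 3) x[3] else NA_character_, "")
  }
  gff$ID <- attr_get(gff$attrs, "ID")
  gff$Parent <- attr_get(gff$attrs, "Parent")
  is_elem <- grepl("retrotransposon|repeat_region|mobile_element", gff$type,
                   ignore.case = TRUE)
  is_ltr <- grepl("long_terminal_repeat", gff$type, ignore.case = TRUE)
  elems <- gff[is_elem, , drop = FALSE]
  ltrs <- gff[is_ltr, , drop = FALSE]
  rows <- list(); skipped <- 0L
  for (i in seq_len(nrow(elems))) {
    id <- elems$ID[i]
    mine <- ltrs[!is.na(ltrs$Parent) & ltrs$Parent == id, , drop = FALSE]
    if (nrow(mine) != 2) {
      skipped <- skipped + 1L
      warning("element ", id, " lacks two LTR sub-features; skipped",
              call. = FALSE)
      next
    }
    mine <- mine[order(mine$start), ]
    rows[[length(rows) + 1L]] <- data.frame(
      id = id, chrom = elems$chrom[i],
      start = elems$start[i] - 1L, end = elems$end[i],
      ltr5_start = mine$start[1] - 1L, ltr5_end = mine$end[1],
      ltr3_start = mine$start[2] - 1L, ltr3_end = mine$end[2],
      family = attr_get(elems$attrs[i], "family") %|NA|% "unknown",
      superfamily = attr_get(elems$attrs[i], "superfamily") %|NA|% "unknown",
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), chrom = character(), start = integer(),
               end = integer(), ltr5_start = integer(), ltr5_end = integer(),
               ltr3_start = integer(), ltr3_end = integer(),
               family = character(), superfamily = character())
  if (!is.null(genome)) {
    len <- nchar(genome[out$chrom])
    if (any(out$end > len | out$start < 0))
      stop("element coordinates outside chromosome bounds")
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("ltr_elements", "data.frame")
  out
}

`%|NA|%` <- function(a, b) ifelse(is.na(a), b, a)

#' Write LTR elements as GFF3 (1-based inclusive)
#' @param elements an `ltr_elements` data.frame
#' @param path output file
#' @export
write_ltr_gff3 <- function(elements, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(elements))) {
    e <- elements[i, ]
    writeLines(c(
      sprintf("%s\tcentroscape\tLTR_retrotransposon\t%d\t%d\t.\t+\t.\tID=%s;family=%s;superfamily=%s",
              e$chrom, e$start + 1L, e$end, e$id, e$family, e$superfamily),
      sprintf("%s\tcentroscape\tlong_terminal_repeat\t%d\t%d\t.\t+\t.\tID=%s_ltr5;Parent=%s",
              e$chrom, e$ltr5_start + 1L, e$ltr5_end, e$id, e$id),
      sprintf("%s\tcentroscape\tlong_terminal_repeat\t%d\t%d\t.\t+\t.\tID=%s_ltr3;Parent=%s",
              e$chrom, e$ltr3_start + 1L, e$ltr3_end, e$id, e$id)), con)
  }
  invisible(path)
}

#' Date LTR elements from 5'/3' LTR divergence
#'
#' Aligns each element's two LTR copies (banded global alignment), takes the
#' observed mismatch fraction over match/mismatch columns (gap columns
#' excluded), corrects it with the chosen substitution model, and converts
#' to age: T = K / (2 mu), reported in MYA.  Saturated divergences (beyond
#' the model's domain) yield `NA` age with `reliable = FALSE`.
#'
#' @param elements an `ltr_elements` data.frame
#' @param genome named character vector of chromosome sequences
#' @param mu substitution rate per site per year (default 1.5e-8)
#' @param model "JC69" (default) or "K2P"
#' @param young_threshold age boundary in MYA for [classify_age()]
#' @return the elements with `p_obs`, `K`, `age_mya`, `age_class`,
#'   `reliable` columns added
#' @export
estimate_age <- function(elements, genome, mu = 1.5e-8,
                         model = c("JC69", "K2P"), young_threshold = 0.5) {
  model <- match.arg(model)
  n <- nrow(elements)
  p_obs <- K <- rep(NA_real_, n)
  reliable <- rep(TRUE, n)
  for (i in seq_len(n)) {
    chrom <- genome[[elements$chrom[i]]]
    a <- substr(chrom, elements$ltr5_start[i] + 1L, elements$ltr5_end[i])
    b <- substr(chrom, elements$ltr3_start[i] + 1L, elements$ltr3_end[i])
    g <- global_identity(a, b)
    p_obs[i] <- g$p_obs_gapless
    if (model == "JC69") {
      if (p_obs[i] >= 0.75) { reliable[i] <- FALSE; next }
      K[i] <- jc69_distance(p_obs[i])
    } else {
      # without per-column transition/transversion splitting from the
      # aligner, assume the JC ratio p:q = 1:2 of total mismatch
      p <- p_obs[i] / 3; q <- 2 * p_obs[i] / 3
      if (1 - 2 * p - q <= 0 || 1 - 2 * q <= 0) { reliable[i] <- FALSE; next }
      K[i] <- k2p_distance(p, q)
    }
  }
  elements$p_obs <- p_obs
  elements$K <- K
  elements$age_mya <- K / (2 * mu) / 1e6
  age_class <- rep(NA_character_, n)
  ok <- !is.na(elements$age_mya)
  age_class[ok] <- classify_age(elements$age_mya[ok], young_threshold)
  elements$age_class <- age_class
  elements$reliable <- reliable
  attr(elements, "mu") <- mu
  attr(elements, "model") <- model
  elements
}

#' Classify element age as young or old
#'
#' Young: age <= threshold (default 0.5 MYA); old otherwise.
#'
#' @param age_mya numeric ages in MYA
#' @param threshold boundary in MYA (default 0.5; the boundary itself is
#'   young)
#' @return character vector "young"/"old"
#' @export
classify_age <- function(age_mya, threshold = 0.5) {
  if (any(!is.finite(age_mya))) stop("age must be finite")
  ifelse(age_mya <= threshold, "young", "old")
}

#' Detect nested LTR insertions by span containment
#'
#' Emits (parent, child) for every pair where the child's span lies strictly
#' inside the parent's span; chains produce one pair per ancestor.  A pair
#' is flagged inconsistent when the child's estimated age exceeds the
#' parent's by more than `age_tolerance`.
#'
#' @param elements an `ltr_elements` data.frame (dated or not)
#' @param age_tolerance MYA slack for the parent-older check (default 0.1)
#' @return data.frame `parent_id`, `child_id`, `consistent`
#' @export
detect_nested <- function(elements, age_tolerance = 0.1) {
  parts <- if ("chrom" %in% names(elements))
    split(elements, elements$chrom) else list(elements)
  out <- list()
  for (el in parts) {
    n <- nrow(el)
    if (n < 2) next
    el <- el[order(el$start, -el$end), ]
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (el$start[j] >= el$end[i]) break
        if (el$start[j] > el$start[i] && el$end[j] < el$end[i]) {
          consistent <- TRUE
          if ("age_mya" %in% names(el) &&
              !is.na(el$age_mya[i]) && !is.na(el$age_mya[j]))
            consistent <- el$age_mya[j] <= el$age_mya[i] + age_tolerance
          out[[length(out) + 1L]] <-
            data.frame(parent_id = el$id[i], child_id = el$id[j],
                       consistent = consistent, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(parent_id = character(), child_id = character(),
                      consistent = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compartment x family composition and age summary
#'
#' @param elements dated `ltr_elements` with a `compartment` column (see
#'   [assign_compartments()])
#' @param by "family" or "superfamily"
#' @return data.frame: compartment, group, n, percent (within compartment),
#'   mean_age_mya, median_age_mya (unreliable ages excluded from the means)
#' @export
composition_table <- function(elements, by = c("family", "superfamily")) {
  by <- match.arg(by)
  if (!"compartment" %in% names(elements))
    stop("elements must carry a compartment column")
  grp <- interaction(elements$compartment, elements[[by]], drop = TRUE)
  rows <- lapply(split(elements, grp), function(d) {
    ages <- if ("reliable" %in% names(d)) d$age_mya[d$reliable] else d$age_mya
    data.frame(compartment = d$compartment[1], group = d[[by]][1],
               n = nrow(d),
               mean_age_mya = mean(ages, na.rm = TRUE),
               median_age_mya = stats::median(ages, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tot <- tapply(out$n, out$compartment, sum)
  out$percent <- 100 * out$n / as.numeric(tot[out$compartment])
  out <- out[order(out$compartment, -out$n),
             c("compartment", "group", "n", "percent", "mean_age_mya",
               "median_age_mya")]
  rownames(out) <- NULL
  out
}

#' Simplified structural detection of full-length LTR elements
#'
#' A light-weight finder for annotation-free synthetic runs: exact-k-mer
#' anchored near-identical repeat pairs within a plausible element-length
#' window, trimmed to TG...CA ends, deduplicated so each LTR copy belongs to
#' one element.  Not equivalent to LTR_retriever: no target-site-duplication
#' or internal-domain evidence is used.
#'
#' @param genome named character vector of chromosome sequences
#' @param ltr_range allowed LTR length range in bp (default 150..3000)
#' @param dist_range allowed 5'-to-3' LTR start distance range (default
#'   1000..25000)
#' @param end_slack bp searched around repeat ends for the TG / CA motif
#'   (default 6)
#' @return an `ltr_elements` data.frame (family/superfamily "unknown")
#' @export
find_ltr_elements <- function(genome, ltr_range = c(150L, 3000L),
                              dist_range = c(1000L, 25000L), end_slack = 6L) {
  rows <- list()
  for (chrom in names(genome)) {
    s <- genome[[chrom]]
    cand <- cpp_find_repeat_pairs(s, 24L, dist_range[1], dist_range[2],
                                  80L, 12L)
    if (nrow(cand) == 0) next
    len <- cand$end1 - cand$start1
    cand <- cand[len >= ltr_range[1] & len <= ltr_range[2], , drop = FALSE]
    if (nrow(cand) == 0) next
    # snap ends to TG...CA (both copies, consistent offset)
    snap <- function(a1, b1, a2, b2) {
      for (ds in 0:end_slack) for (sg in c(1L, -1L)) {
        d <- sg * ds
        if (substr(s, a1 + d + 1, a1 + d + 2) == "TG" &&
            substr(s, a2 + d + 1, a2 + d + 2) == "TG") {
          for (de in 0:end_slack) for (sg2 in c(1L, -1L)) {
            e <- sg2 * de
            if (substr(s, b1 + e - 1, b1 + e) == "CA" &&
                substr(s, b2 + e - 1, b2 + e) == "CA")
              return(c(a1 + d, b1 + e, a2 + d, b2 + e))
          }
          return(NULL)
        }
      }
      NULL
    }
    kept <- list()
    for (i in seq_len(nrow(cand))) {
      sn <- snap(cand$start1[i], cand$end1[i], cand$start2[i], cand$end2[i])
      if (is.null(sn)) next
      if (sn[2] - sn[1] < ltr_range[1]) next
      kept[[length(kept) + 1L]] <- sn
    }
    if (length(kept) == 0) next
    km <- do.call(rbind, kept)
    km <- km[order(km[, 4] - km[, 1]), , drop = FALSE] # compact spans first
    claimed <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(nrow(km))) {
      l5 <- km[i, 1:2]; l3 <- km[i, 3:4]
      overlaps <- function(iv) {
        if (nrow(claimed) == 0) return(FALSE)
        ov <- pmin(claimed[, 2], iv[2]) - pmax(claimed[, 1], iv[1])
        any(ov > 0.5 * (iv[2] - iv[1]))
      }
      if (overlaps(l5) || overlaps(l3)) next
      claimed <- rbind(claimed, l5, l3)
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("%s_fl%04d", chrom, length(rows) + 1L), chrom = chrom,
        start = km[i, 1], end = km[i, 4],
        ltr5_start = km[i, 1], ltr5_end = km[i, 2],
        ltr3_start = km[i, 3], ltr3_end = km[i, 4],
        family = "unknown", superfamily = "unknown",
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), chrom = character(), start = integer(),
               end = integer(), ltr5_start = integer(), ltr5_end = integer(),
               ltr3_start = integer(), ltr3_end = integer(),
               family = character(), superfamily = character())
  rownames(out) <- NULL
  class(out) <- c("ltr_elements", "data.frame")
  out
}
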
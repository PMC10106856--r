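# Synthetic chromosome simulator with planted ground truth.
#
# Layout: telomere - arm - pericentromere - centromere - pericentromere -
# arm - telomere.  Satellite monomers are tiled head-to-tail with small
# per-copy divergence; full-length LTR elements are inserted with ages drawn
# per compartment (each LTR copy mutated on its own branch so the pairwise
# LTR divergence has expectation 2*mu*T); a hidden repeat unit is tiled into
# the pericentromere and embedded into a subset of elements.  All planted
# coordinates, ages, parents and copy counts are recorded.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
      else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    })
    set.seed(seed)
  }
  force(code)
}

# truncated-at-zero normal draws (rejection sampling)
rtnorm0 <- function(n, mean, sd) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x >= 0])
  }
  out[seq_len(n)]
}

#' Random DNA sequence
#'
#' i.i.d. bases at the given GC fraction, drawn from the current RNG stream
#' (or from `seed` if given).
#'
#' @param n length in bp
#' @param gc GC fraction (default 0.5)
#' @param seed optional integer seed
#' @return a nucleotide string
#' @export
random_dna <- function(n, gc = 0.5, seed = NULL) {
  with_seed(seed, cpp_random_seq(as.integer(n), gc))
}

#' Mutate a sequence under a Jukes-Cantor substitution process
#'
#' Each site is substituted (uniformly among the three alternative bases)
#' with probability 3/4 (1 - exp(-4K/3)), the JC69 transition probability for
#' branch length `K`, so the expected observed mismatch fraction against the
#' input equals that value and two independently mutated copies diverge as a
#' JC branch of 2K.  Substitution-only: the output has the same length.
#'
#' @param seq nucleotide string over ACGT
#' @param K branch length in substitutions per site (>= 0)
#' @param seed optional integer seed
#' @return mutated sequence
#' @export
mutate_sequence <- function(seq, K, seed = NULL) {
  check_seq(seq)
  if (K < 0) stop("K must be nonnegative")
  p <- 0.75 * (1 - exp(-4 * K / 3))
  with_seed(seed, cpp_mutate(seq, p))
}

#' Expected observed mismatch fraction for a JC branch of length K
#' @param K substitutions per site
#' @return expected mismatch fraction 3/4 (1 - exp(-4K/3))
#' @export
jc69_p_expected <- function(K) 0.75 * (1 - exp(-4 * K / 3))

#' Tile a satellite monomer into an array
#'
#' Head-to-tail copies, each independently mutated at per-copy divergence
#' `K`, truncated to `span` bp.
#'
#' @param monomer monomer sequence
#' @param span array length in bp
#' @param K per-copy JC branch length (default 0.02)
#' @return list with `seq` and `n_copies` (complete copies)
#' @export
satellite_array <- function(monomer, span, K = 0.02) {
  m <- nchar(monomer)
  n <- ceiling(span / m)
  p <- 0.75 * (1 - exp(-4 * K / 3))
  copies <- vapply(seq_len(n), function(i) cpp_mutate(monomer, p), character(1))
  list(seq = substr(paste0(copies, collapse = ""), 1L, span),
       n_copies = floor(span / m))
}

#' LTR retrotransposon family catalogue
#'
#' The twelve family labels used by the simulator and their superfamilies.
#' @return data.frame with `family` and `superfamily`
#' @export
ltr_families <- function() {
  data.frame(
    family = c("ALE", "Angela", "Bianca", "Ikeros", "Ivana", "SIRE", "TAR",
               "Tork", "CRM", "Tekay", "Retand", "Galadriel"),
    superfamily = c(rep("Copia", 8), rep("Gypsy", 4)),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults describe a 3 Mb chromosome with 3 kb telomeres (TTTAGGG), a
#' 500 kb centromere built from a 176 bp satellite, two 300 kb
#' pericentromeres built from 238 bp and 1022 bp satellites, compartment LTR
#' ages (mean, sd, truncated at 0) of 0.14/0.15 (centromere), 0.51/0.15
#' (pericentromere) and 0.32/0.15 (arms) MYA, mu = 1.5e-8 substitutions per
#' site per year, 10% nested insertions, and a 630 bp hidden repeat with 300
#' pericentromeric copies, 20 of the pericentromeric elements carrying an
#' embedded copy.  Compartment spans are final region sizes: satellite cores
#' are shrunk to absorb the inserted elements.
#'
#' @param chromosome_length total chromosome length in bp
#' @param arm_gc GC fraction of arm background sequence
#' @param tel_span telomere length in bp (each end)
#' @param cent_span centromere span in bp
#' @param peri_span pericentromere span in bp (each side)
#' @param telomere_motif telomeric repeat unit
#' @param probe_lengths monomer lengths per role (list with `centromeric`
#'   and `pericentromeric` integer vectors)
#' @param satellite_k per-satellite-copy JC divergence
#' @param n_ltr named-count list per compartment
#'   (`centromere`/`pericentromere`/`arm`, names are family labels)
#' @param ages per-compartment `c(mean, sd)` of insertion age in MYA
#' @param mu substitution rate per site per year
#' @param nested_fraction fraction of elements inserted inside an earlier
#'   element of the same compartment
#' @param ltr_len_range,internal_len_range template LTR / internal length
#'   ranges in bp
#' @param hidden_repeat list(length, n_peri, n_embed) or NULL for none
#' @param chrom_name sequence name
#' @param seed integer seed; fixed seed gives byte-identical output
#' @return a `sim_config` list
#' @export
sim_config <- function(chromosome_length = 3e6,
                       arm_gc = 0.36,
                       tel_span = 3000,
                       cent_span = 5e5,
                       peri_span = 3e5,
                       telomere_motif = "TTTAGGG",
                       probe_lengths = list(centromeric = 176L,
                                            pericentromeric = c(238L, 1022L)),
                       satellite_k = 0.02,
                       n_ltr = list(
                         centromere = c(ALE = 28, CRM = 14, Angela = 4, Ivana = 4),
                         pericentromere = c(CRM = 15, Tekay = 14, Retand = 6, Athila = 5),
                         arm = c(Angela = 8, ALE = 4, Tekay = 4)),
                       ages = list(centromere = c(mean = 0.14, sd = 0.15),
                                   pericentromere = c(mean = 0.51, sd = 0.15),
                                   arm = c(mean = 0.32, sd = 0.15)),
                       mu = 1.5e-8,
                       nested_fraction = 0.1,
                       ltr_len_range = c(300, 800),
                       internal_len_range = c(2000, 4000),
                       hidden_repeat = list(length = 630, n_peri = 300, n_embed = 20),
                       chrom_name = "chr1",
                       seed = 1L) {
  cfg <- list(chromosome_length = as.integer(chromosome_length),
              arm_gc = arm_gc, tel_span = as.integer(tel_span),
              cent_span = as.integer(cent_span),
              peri_span = as.integer(peri_span),
              telomere_motif = telomere_motif,
              probe_lengths = probe_lengths,
              satellite_k = satellite_k, n_ltr = n_ltr, ages = ages,
              mu = mu, nested_fraction = nested_fraction,
              ltr_len_range = ltr_len_range,
              internal_len_range = internal_len_range,
              hidden_repeat = hidden_repeat,
              chrom_name = chrom_name, seed = as.integer(seed))
  if (cfg$mu <= 0) stop("mu must be positive")
  occupied <- cfg$cent_span + 2 * cfg$peri_span + 2 * cfg$tel_span
  if (occupied >= cfg$chromosome_length)
    stop("infeasible layout: spans (", occupied,
         " bp) exceed chromosome_length (", cfg$chromosome_length, " bp)")
  structure(cfg, class = "sim_config")
}

#' Configuration for hidden-repeat discovery runs
#'
#' The discovery study conditions: enlarged pericentromeres (2 x 750 kb)
#' holding 1200 copies of a 630 bp hidden unit, 80 pericentromeric elements
#' in four families of twenty (so no LTR family reaches the 50-occurrence
#' filter), 60 of them carrying an embedded hidden copy.
#'
#' @param seed integer seed
#' @param with_hidden plant the hidden repeat (set FALSE for null genomes)
#' @param ... overrides passed to [sim_config()]
#' @return a `sim_config`
#' @export
discovery_config <- function(seed = 1L, with_hidden = TRUE, ...) {
  sim_config(chromosome_length = 2.8e6,
             cent_span = 2e5,
             peri_span = 7.5e5,
             n_ltr = list(
               centromere = c(ALE = 10, CRM = 5),
               pericentromere = c(CRM = 20, Tekay = 20, Retand = 20, Athila = 20),
               arm = c(Angela = 4, ALE = 2)),
             hidden_repeat = if (with_hidden)
               list(length = 630, n_peri = 1200, n_embed = 60) else NULL,
             seed = seed, ...)
}

# family -> superfamily lookup (families outside the catalogue: "unknown")
family_superfamily <- function(family) {
  fam <- ltr_families()
  extra <- c(Athila = "Gypsy")
  out <- fam$superfamily[match(family, fam$family)]
  out[is.na(out)] <- unname(extra[family[is.na(out)]])
  out[is.na(out)] <- "unknown"
  out
}

# build family templates from the current RNG stream
make_templates <- function(families, ltr_len_range, internal_len_range, gc = 0.42) {
  templates <- list()
  for (f in families) {
    llen <- round(runif(1, ltr_len_range[1], ltr_len_range[2]))
    ilen <- round(runif(1, internal_len_range[1], internal_len_range[2]))
    ltr <- paste0("TG", cpp_random_seq(llen - 4L, gc), "CA")
    templates[[f]] <- list(family = f,
                           superfamily = family_superfamily(f),
                           ltr = ltr,
                           internal = cpp_random_seq(ilen, gc))
  }
  templates
}

#' Insert an aged full-length LTR element into a sequence
#'
#' Builds an element from a template (two identical LTR copies flanking an
#' internal region), ages it by mutating each LTR copy and the internal
#' region on independent JC branches of length `mu * T`, optionally embeds a
#' foreign sequence in the internal region, and splices it into `seq` at
#' `position` (0-based: the element occupies `[position, position + L)`).
#'
#' @param seq recipient nucleotide string
#' @param template list with `family`, `superfamily`, `ltr`, `internal`
#' @param true_age insertion age in MYA
#' @param position 0-based insertion offset in `[0, nchar(seq)]`
#' @param mu substitution rate per site per year
#' @param embed optional sequence embedded at a random offset of the
#'   internal region (mutated on the same branch)
#' @param seed optional integer seed
#' @return list with `seq` (lengthened sequence) and `element` (one-row
#'   data.frame: coordinates of span and both LTRs, family, superfamily,
#'   true age, embedded-copy interval or NA)
#' @export
plant_ltr <- function(seq, template, true_age, position, mu = 1.5e-8,
                      embed = NULL, seed = NULL) {
  with_seed(seed, {
    if (position < 0 || position > nchar(seq))
      stop("position outside sequence")
    if (true_age < 0) stop("true_age must be nonnegative")
    K <- mu * true_age * 1e6
    p <- 0.75 * (1 - exp(-4 * K / 3))
    ltr5 <- cpp_mutate(template$ltr, p)
    ltr3 <- cpp_mutate(template$ltr, p)
    internal <- template$internal
    emb_off <- NA_integer_; emb_len <- NA_integer_
    if (!is.null(embed)) {
      emb_off <- floor(runif(1, 10, nchar(internal) - 10))
      emb_len <- nchar(embed)
      internal <- paste0(substr(internal, 1, emb_off),
                         cpp_mutate(embed, p),
                         substr(internal, emb_off + 1, nchar(internal)))
    }
    internal <- cpp_mutate(internal, p)
    elem_seq <- paste0(ltr5, internal, ltr3)
    L <- nchar(elem_seq); ll <- nchar(template$ltr)
    new_seq <- paste0(substr(seq, 1, position), elem_seq,
                      substr(seq, position + 1, nchar(seq)))
    element <- data.frame(
      start = position, end = position + L,
      ltr5_start = position, ltr5_end = position + ll,
      ltr3_start = position + L - ll, ltr3_end = position + L,
      family = template$family, superfamily = template$superfamily,
      true_age_mya = true_age,
      embed_start = if (is.na(emb_off)) NA_integer_ else position + ll + emb_off,
      embed_end = if (is.na(emb_off)) NA_integer_ else position + ll + emb_off + emb_len,
      stringsAsFactors = FALSE)
    list(seq = new_seq, element = element)
  })
}

# shift tracked intervals for an insertion of length L at point p.
# intervals strictly containing p stretch; intervals at or after p shift.
shift_interval <- function(s, e, p, L) {
  stretch <- !is.na(s) & s < p & e > p
  after <- !is.na(s) & s >= p
  s[after] <- s[after] + L
  e[after] <- e[after] + L
  e[stretch] <- e[stretch] + L
  list(s = s, e = e)
}

# build one pericentromere core: satellite runs interleaved with hidden
# copies; returns seq, hidden copy intervals, per-monomer copy counts
build_peri_core <- function(span, monomers, n_hidden, hidden_seq,
                            satellite_k, hidden_k = 0.02) {
  hid_len <- if (n_hidden > 0) nchar(hidden_seq) else 0L
  sat_total <- span - n_hidden * hid_len
  if (sat_total < 0.2 * span)
    stop("infeasible layout: hidden repeat copies exceed pericentromere span")
  # satellite stretch lengths between hidden copies
  n_runs <- n_hidden + 1
  w <- runif(n_runs, 0.5, 1.5)
  run_len <- floor(sat_total * w / sum(w))
  run_len[n_runs] <- sat_total - sum(run_len[-n_runs])
  segs <- character(0)
  hid_s <- integer(0)
  counts <- setNames(numeric(length(monomers)), names(monomers))
  pos <- 0L
  p_hid <- 0.75 * (1 - exp(-4 * hidden_k / 3))
  for (i in seq_len(n_runs)) {
    mi <- if (length(monomers) == 1L) 1L else sample(length(monomers), 1L)
    arr <- satellite_array(monomers[[mi]], run_len[i], satellite_k)
    counts[mi] <- counts[mi] + arr$n_copies
    segs <- c(segs, arr$seq)
    pos <- pos + nchar(arr$seq)
    if (i <= n_hidden) {
      hid_s <- c(hid_s, pos)
      segs <- c(segs, cpp_mutate(hidden_seq, p_hid))
      pos <- pos + hid_len
    }
  }
  list(seq = paste0(segs, collapse = ""),
       hidden = if (n_hidden > 0)
         data.frame(start = hid_s, end = hid_s + hid_len) else
           data.frame(start = integer(), end = integer()),
       counts = counts)
}

# insert the compartment's elements into its core sequence; returns the
# expanded sequence, the element table (compartment-local coordinates) and
# updated hidden-copy intervals
insert_elements <- function(core, plan, templates, hidden_seq, mu,
                            nested_fraction, hidden_df) {
  elements <- NULL
  seq <- core
  hs <- hidden_df$start; he <- hidden_df$end
  for (i in seq_len(nrow(plan))) {
    fam <- plan$family[i]
    tpl <- templates[[fam]]
    embed <- if (plan$embed[i]) hidden_seq else NULL
    elen <- 2L * nchar(tpl$ltr) + nchar(tpl$internal) +
      (if (plan$embed[i]) nchar(hidden_seq) else 0L)
    nest <- runif(1) < nested_fraction && !is.null(elements) && nrow(elements) > 0
    parent <- NA_integer_
    pos <- NA_integer_
    age <- plan$age[i]
    for (try in seq_len(2000)) {
      if (nest) {
        parent <- sample(nrow(elements), 1L)
        lo <- elements$ltr5_end[parent] + 5L
        hi <- elements$ltr3_start[parent] - 5L
        if (hi <= lo) { nest <- FALSE; next }
        pos <- floor(runif(1, lo, hi))
      } else {
        parent <- NA_integer_
        pos <- floor(runif(1, 1, nchar(seq) - 1))
      }
      # position must not fall inside any other element span or hidden copy
      in_elem <- if (is.null(elements)) integer(0) else
        which(elements$start < pos & elements$end > pos)
      bad_elem <- if (nest) setdiff(in_elem, elem_ancestors(elements, parent))
                  else in_elem
      in_hid <- any(hs < pos & he > pos)
      if (length(bad_elem) == 0 && !in_hid) break
      pos <- NA_integer_
    }
    if (is.na(pos)) stop("could not place element after 2000 tries")
    if (nest && age > elements$true_age_mya[parent])
      age <- elements$true_age_mya[parent] * runif(1)
    res <- plant_ltr(seq, tpl, age, pos, mu, embed = embed)
    L <- res$element$end - res$element$start
    if (!is.null(elements) && nrow(elements) > 0) {
      for (cols in list(c("start", "end"), c("ltr5_start", "ltr5_end"),
                        c("ltr3_start", "ltr3_end"),
                        c("embed_start", "embed_end"))) {
        sh <- shift_interval(elements[[cols[1]]], elements[[cols[2]]], pos, L)
        elements[[cols[1]]] <- sh$s; elements[[cols[2]]] <- sh$e
      }
    }
    if (length(hs) > 0) {
      sh <- shift_interval(hs, he, pos, L)
      hs <- sh$s; he <- sh$e
    }
    row <- res$element
    row$parent <- parent
    elements <- rbind(elements, row)
    seq <- res$seq
  }
  if (is.null(elements))
    elements <- data.frame(start = integer(), end = integer(),
                           ltr5_start = integer(), ltr5_end = integer(),
                           ltr3_start = integer(), ltr3_end = integer(),
                           family = character(), superfamily = character(),
                           true_age_mya = numeric(), embed_start = integer(),
                           embed_end = integer(), parent = integer())
  list(seq = seq, elements = elements,
       hidden = data.frame(start = hs, end = he))
}

# indices of all ancestors of element i via the parent column
elem_ancestors <- function(elements, i) {
  out <- integer(0)
  while (!is.na(i)) {
    out <- c(out, i)
    i <- elements$parent[i]
  }
  out
}

#' Simulate a chromosome with planted ground truth
#'
#' @param config a [sim_config()]
#' @return list with `seq` (named nucleotide string), `truth` (list:
#'   `regions`, `elements`, `hidden_copies`, `hidden_seq`, `probes`,
#'   `probe_counts`, `nested_pairs`) and `config`
#' @export
simulate_chromosome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    chrom <- config$chrom_name
    # probes
    cent_mono <- lapply(config$probe_lengths$centromeric, function(n)
      cpp_random_seq(as.integer(n), 0.42))
    names(cent_mono) <- paste0("CentSR_", config$probe_lengths$centromeric)
    peri_mono <- lapply(config$probe_lengths$pericentromeric, function(n)
      cpp_random_seq(as.integer(n), 0.42))
    names(peri_mono) <- paste0("PeriSR_", config$probe_lengths$pericentromeric)
    probes <- data.frame(
      id = c(names(cent_mono), names(peri_mono), "BrSTR"),
      role = c(rep("centromeric", length(cent_mono)),
               rep("pericentromeric", length(peri_mono)), "telomeric"),
      seq = c(unlist(cent_mono), unlist(peri_mono), config$telomere_motif),
      stringsAsFactors = FALSE)
    rownames(probes) <- NULL
    # family templates and element plans per compartment
    fams <- unique(unlist(lapply(config$n_ltr, names)))
    templates <- make_templates(fams, config$ltr_len_range,
                                config$internal_len_range)
    hidden_seq <- if (!is.null(config$hidden_repeat))
      cpp_random_seq(as.integer(config$hidden_repeat$length), 0.40) else NULL
    make_plan <- function(compartment) {
      counts <- config$n_ltr[[compartment]]
      if (is.null(counts) || sum(counts) == 0)
        return(data.frame(family = character(), age = numeric(),
                          embed = logical()))
      fam <- rep(names(counts), counts)
      a <- config$ages[[compartment]]
      data.frame(family = fam,
                 age = rtnorm0(length(fam), a[["mean"]], a[["sd"]]),
                 embed = FALSE, stringsAsFactors = FALSE)
    }
    plan_cent <- make_plan("centromere")
    # pericentromeric elements are split over the two flanks
    plan_peri1 <- make_plan("pericentromere")
    plan_peri2 <- plan_peri1[integer(0), , drop = FALSE]
    n_peri_total <- nrow(plan_peri1)
    if (n_peri_total > 0) {
      half <- sample(n_peri_total, floor(n_peri_total / 2))
      plan_peri2 <- plan_peri1[half, , drop = FALSE]
      plan_peri1 <- plan_peri1[setdiff(seq_len(n_peri_total), half), , drop = FALSE]
    }
    n_embed <- if (!is.null(config$hidden_repeat)) config$hidden_repeat$n_embed else 0
    if (n_embed > nrow(plan_peri1) + nrow(plan_peri2))
      stop("infeasible layout: n_embed exceeds pericentromeric element count")
    if (n_embed > 0) {
      emb1 <- min(nrow(plan_peri1), ceiling(n_embed / 2))
      emb2 <- n_embed - emb1
      if (emb2 > nrow(plan_peri2)) { emb1 <- emb1 + (emb2 - nrow(plan_peri2)); emb2 <- nrow(plan_peri2) }
      if (nrow(plan_peri1) > 0 && emb1 > 0)
        plan_peri1$embed[sample(nrow(plan_peri1), emb1)] <- TRUE
      if (nrow(plan_peri2) > 0 && emb2 > 0)
        plan_peri2$embed[sample(nrow(plan_peri2), emb2)] <- TRUE
    }
    plan_arm <- make_plan("arm")
    arm_half <- if (nrow(plan_arm) > 0) sample(nrow(plan_arm), floor(nrow(plan_arm) / 2)) else integer(0)
    plan_arm1 <- plan_arm[setdiff(seq_len(nrow(plan_arm)), arm_half), , drop = FALSE]
    plan_arm2 <- plan_arm[arm_half, , drop = FALSE]

    elem_len <- function(plan) {
      if (nrow(plan) == 0) return(0L)
      sum(vapply(seq_len(nrow(plan)), function(i) {
        tpl <- templates[[plan$family[i]]]
        2L * nchar(tpl$ltr) + nchar(tpl$internal) +
          (if (plan$embed[i]) nchar(hidden_seq) else 0L)
      }, numeric(1)))
    }
    # core sizes: compartment spans are final sizes, elements are absorbed
    cent_core_len <- config$cent_span - elem_len(plan_cent)
    peri1_core_len <- config$peri_span - elem_len(plan_peri1)
    peri2_core_len <- config$peri_span - elem_len(plan_peri2)
    if (cent_core_len < 0.2 * config$cent_span ||
        peri1_core_len < 0.1 * config$peri_span ||
        peri2_core_len < 0.1 * config$peri_span)
      stop("infeasible layout: planted elements exceed compartment span")
    arm_total <- config$chromosome_length - config$cent_span -
      2L * config$peri_span - 2L * config$tel_span
    arm1_len <- floor(arm_total / 2)
    arm2_len <- arm_total - arm1_len
    arm1_core_len <- arm1_len - elem_len(plan_arm1)
    arm2_core_len <- arm2_len - elem_len(plan_arm2)
    if (arm1_core_len < 0 || arm2_core_len < 0)
      stop("infeasible layout: arm elements exceed arm span")

    # telomeres: exact motif tiling with light divergence
    tel <- function() satellite_array(config$telomere_motif,
                                      config$tel_span, K = 0.005)$seq
    tel1 <- tel(); tel2 <- tel()
    # arms
    build_arm <- function(core_len, plan) {
      core <- cpp_random_seq(as.integer(core_len), config$arm_gc)
      insert_elements(core, plan, templates, hidden_seq, config$mu,
                      config$nested_fraction,
                      data.frame(start = integer(), end = integer()))
    }
    arm1 <- build_arm(arm1_core_len, plan_arm1)
    arm2 <- build_arm(arm2_core_len, plan_arm2)
    # pericentromeres
    n_hid <- if (!is.null(config$hidden_repeat)) config$hidden_repeat$n_peri else 0L
    nh1 <- floor(n_hid / 2); nh2 <- n_hid - nh1
    build_peri <- function(core_len, n_hidden, plan) {
      core <- build_peri_core(core_len, peri_mono, n_hidden, hidden_seq,
                              config$satellite_k)
      ins <- insert_elements(core$seq, plan, templates, hidden_seq,
                             config$mu, config$nested_fraction, core$hidden)
      list(seq = ins$seq, elements = ins$elements, hidden = ins$hidden,
           counts = core$counts)
    }
    peri1 <- build_peri(peri1_core_len, nh1, plan_peri1)
    peri2 <- build_peri(peri2_core_len, nh2, plan_peri2)
    # centromere
    cent_core <- satellite_array(cent_mono[[1]], cent_core_len,
                                 config$satellite_k)
    cent <- insert_elements(cent_core$seq, plan_cent, templates, hidden_seq,
                            config$mu, config$nested_fraction,
                            data.frame(start = integer(), end = integer()))

    segs <- list(tel1 = tel1, arm1 = arm1$seq, peri1 = peri1$seq,
                 cent = cent$seq, peri2 = peri2$seq, arm2 = arm2$seq,
                 tel2 = tel2)
    lens <- vapply(segs, nchar, numeric(1))
    off <- cumsum(c(0, lens[-length(lens)]))
    names(off) <- names(segs)
    seq <- paste0(unlist(segs), collapse = "")

    regions <- data.frame(
      chrom = chrom,
      start = unname(off),
      end = unname(off + lens),
      role = c("telomere", "arm", "pericentromere", "centromere",
               "pericentromere", "arm", "telomere"),
      stringsAsFactors = FALSE)

    globalize <- function(part, offset, compartment) {
      el <- part$elements
      if (nrow(el) == 0) return(NULL)
      for (col in c("start", "end", "ltr5_start", "ltr5_end", "ltr3_start",
                    "ltr3_end", "embed_start", "embed_end"))
        el[[col]] <- el[[col]] + offset
      el$compartment <- compartment
      el
    }
    elements <- rbind(
      globalize(arm1, off[["arm1"]], "arm"),
      globalize(peri1, off[["peri1"]], "pericentromere"),
      globalize(cent, off[["cent"]], "centromere"),
      globalize(peri2, off[["peri2"]], "pericentromere"),
      globalize(arm2, off[["arm2"]], "arm"))
    nested_pairs <- data.frame(parent_id = character(), child_id = character())
    if (!is.null(elements) && nrow(elements) > 0) {
      # per-part parent indices were local; rebuild ids and global pairs
      parts <- list(arm1 = arm1, peri1 = peri1, cent = cent, peri2 = peri2,
                    arm2 = arm2)
      ids <- character(0); pid <- character(0); cid <- character(0)
      counter <- 0L
      for (pn in names(parts)) {
        el <- parts[[pn]]$elements
        if (nrow(el) == 0) next
        local_ids <- sprintf("LTR%04d", counter + seq_len(nrow(el)))
        counter <- counter + nrow(el)
        ids <- c(ids, local_ids)
        for (i in seq_len(nrow(el))) {
          anc <- setdiff(elem_ancestors(el, i), i)
          if (length(anc) > 0) {
            pid <- c(pid, local_ids[anc])
            cid <- c(cid, rep(local_ids[i], length(anc)))
          }
        }
      }
      elements$id <- ids
      elements$chrom <- chrom
      elements$parent_id <- NA_character_
      # direct parent only (innermost)
      k <- 0L
      for (pn in names(parts)) {
        el <- parts[[pn]]$elements
        if (nrow(el) == 0) next
        idx <- k + seq_len(nrow(el))
        elements$parent_id[idx] <- ifelse(is.na(el$parent), NA_character_,
                                          elements$id[k + el$parent])
        k <- k + nrow(el)
      }
      nested_pairs <- data.frame(parent_id = pid, child_id = cid,
                                 stringsAsFactors = FALSE)
      elements <- elements[, c("id", "chrom", "start", "end", "ltr5_start",
                               "ltr5_end", "ltr3_start", "ltr3_end", "family",
                               "superfamily", "true_age_mya", "parent_id",
                               "compartment", "embed_start", "embed_end")]
      rownames(elements) <- NULL
    }
    hidden_copies <- rbind(
      if (nrow(peri1$hidden) > 0)
        data.frame(chrom = chrom, start = peri1$hidden$start + off[["peri1"]],
                   end = peri1$hidden$end + off[["peri1"]], where = "pericentromere"),
      if (nrow(peri2$hidden) > 0)
        data.frame(chrom = chrom, start = peri2$hidden$start + off[["peri2"]],
                   end = peri2$hidden$end + off[["peri2"]], where = "pericentromere"))
    if (!is.null(elements) && nrow(elements) > 0) {
      emb <- elements[!is.na(elements$embed_start), , drop = FALSE]
      if (nrow(emb) > 0)
        hidden_copies <- rbind(hidden_copies,
                               data.frame(chrom = chrom, start = emb$embed_start,
                                          end = emb$embed_end, where = "element"))
    }
    probe_counts <- c(setNames(cent_core$n_copies, names(cent_mono)[1]),
                      peri1$counts + peri2$counts)
    seqs <- setNames(seq, chrom)
    truth <- list(regions = regions, elements = elements,
                  hidden_copies = hidden_copies, hidden_seq = hidden_seq,
                  probes = probes, probe_counts = probe_counts,
                  nested_pairs = nested_pairs)
    list(seq = seqs, truth = truth, config = config)
  })
}

#' Simulate a multi-chromosome genome for telomere screening
#'
#' Random-background chromosomes with telomere arrays planted at a chosen
#' subset of ends.
#'
#' @param n_chrom number of chromosomes
#' @param chrom_length length of each chromosome in bp
#' @param present logical matrix `n_chrom x 2` (left/right end has a
#'   telomere); default plants telomeres at 18 of 20 ends, with one
#'   chromosome lacking both
#' @param motif telomeric repeat unit
#' @param tel_span telomere array length in bp
#' @param gc background GC fraction
#' @param seed integer seed
#' @return list with `seqs` (named character vector) and `truth`
#'   (data.frame: chrom, end, planted)
#' @export
simulate_telomere_genome <- function(n_chrom = 10, chrom_length = 2e5,
                                     present = NULL, motif = "TTTAGGG",
                                     tel_span = 3000, gc = 0.36, seed = 1L) {
  if (is.null(present)) {
    present <- matrix(TRUE, n_chrom, 2)
    present[n_chrom, ] <- FALSE
  }
  with_seed(seed, {
    seqs <- character(n_chrom)
    rows <- list()
    for (i in seq_len(n_chrom)) {
      mid <- cpp_random_seq(as.integer(chrom_length - sum(present[i, ]) * tel_span), gc)
      left <- if (present[i, 1]) satellite_array(motif, tel_span, 0.005)$seq else ""
      right <- if (present[i, 2]) satellite_array(motif, tel_span, 0.005)$seq else ""
      seqs[i] <- paste0(left, mid, right)
      rows[[i]] <- data.frame(chrom = sprintf("chr%02d", i),
                              end = c("left", "right"), planted = present[i, ])
    }
    names(seqs) <- sprintf("chr%02d", seq_len(n_chrom))
    list(seqs = seqs, truth = do.call(rbind, rows))
  })
}

#' Write sequences as FASTA
#' @param seqs named character vector of sequences
#' @param path output file
#' @export
write_genome_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file
#' @return named character vector
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write simulation ground truth to a directory
#'
#' Regions as BED (0-based half-open), elements as TSV, hidden repeat as
#' FASTA.
#'
#' @param truth the `truth` component of [simulate_chromosome()]
#' @param dir output directory (created if missing)
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bed(data.frame(chrom = truth$regions$chrom, start = truth$regions$start,
                       end = truth$regions$end, name = truth$regions$role),
            file.path(dir, "regions.bed"))
  if (!is.null(truth$elements))
    write.table(truth$elements, file.path(dir, "elements.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(truth$hidden_seq))
    write_genome_fasta(c(hidden_repeat = truth$hidden_seq),
                       file.path(dir, "hidden_repeat.fa"))
  write.table(truth$probes, file.path(dir, "probes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
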
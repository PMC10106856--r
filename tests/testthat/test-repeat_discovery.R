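# Novel-repeat discovery: self-clustering, occurrence filters, known-repeat
# exclusion.

# elements with a shared unit embedded in a subset, all else unique
make_embedded_set <- function(n_elem = 20, n_embed = 12, unit_len = 400,
                              elem_len = 3000, K = 0.02, seed = 1) {
  set.seed(seed)
  unit <- random_dna(unit_len, 0.45)
  seqs <- vapply(seq_len(n_elem), function(i) {
    body <- random_dna(elem_len, 0.42)
    if (i <= n_embed) {
      at <- sample(200:(elem_len - 200 - unit_len), 1)
      body <- paste0(substr(body, 1, at), mutate_sequence(unit, K),
                     substr(body, at + unit_len + 1, elem_len))
    }
    body
  }, character(1))
  names(seqs) <- sprintf("el%02d", seq_len(n_elem))
  list(seqs = seqs, unit = unit)
}

test_that("an embedded unit clusters with the exact occurrence count", {
  es <- make_embedded_set(n_elem = 20, n_embed = 12, seed = 111)
  cand <- self_cluster(es$seqs)
  expect_gte(nrow(cand), 1)
  top <- cand[1, ]
  expect_identical(top$self_occurrences, 12L)
  # representative covers the planted unit at >= 95% of its length
  h <- local_align(top$seq, es$unit, min_identity = 0.8, min_length = 50)
  expect_gte(max(h$aligned_columns), 0.95 * 400)
})

test_that("all-unique elements produce no multi-element cluster", {
  set.seed(112)
  seqs <- setNames(vapply(1:15, function(i) random_dna(3000, 0.42),
                          character(1)), sprintf("u%02d", 1:15))
  cand <- self_cluster(seqs)
  expect_true(nrow(cand) == 0 || max(cand$self_occurrences) < 2)
  expect_error(self_cluster(seqs[1]), "at least 2")
})

test_that("duplicated element records double the occurrence count", {
  es <- make_embedded_set(n_elem = 10, n_embed = 6, seed = 113)
  once <- self_cluster(es$seqs)
  twice <- self_cluster(setNames(c(es$seqs, es$seqs),
                                 sprintf("d%02d", 1:20)))
  expect_identical(max(twice$self_occurrences),
                   2L * max(once$self_occurrences))
})

test_that("determinism: identical inputs give identical candidates", {
  es <- make_embedded_set(n_elem = 12, n_embed = 8, seed = 114)
  expect_identical(self_cluster(es$seqs), self_cluster(es$seqs))
})

test_that("occurrence filters apply the paper's boundary semantics", {
  # unit with exact planted pericentromere copies to count
  set.seed(115)
  unit <- random_dna(200, 0.45)
  mk_target <- function(n_copies) {
    paste0(paste0(vapply(seq_len(n_copies), function(i)
      paste0(random_dna(80, 0.4), unit), character(1)), collapse = ""),
      random_dna(500, 0.4))
  }
  peri <- c(p1 = mk_target(10))
  cand <- data.frame(unit_id = "u1", seq = unit, length = 200L,
                     self_occurrences = 49L, rep_element = "x",
                     rep_start = 0L, rep_end = 200L, score = 200L)
  class(cand) <- c("candidate_repeats", "data.frame")
  # self_occurrences = 49 < 50: dropped before any peri counting
  expect_identical(nrow(filter_candidates(cand, peri, min_self = 50L,
                                          min_peri_hits = 5L)), 0L)
  # at the threshold (>= min_self) it survives the first filter
  cand$self_occurrences <- 50L
  kept <- filter_candidates(cand, peri, min_self = 50L, min_peri_hits = 5L)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$peri_hits, 10L)
  # peri_hits must strictly exceed min_peri_hits
  expect_identical(nrow(filter_candidates(cand, peri, min_self = 50L,
                                          min_peri_hits = 10L)), 0L)
  expect_error(filter_candidates(cand, character(0)), "empty")
})

test_that("merged hit counting is immune to tandem staircases", {
  set.seed(116)
  unit <- random_dna(150, 0.45)
  # 5 tandem copies with no spacers: staircase alignments merge to 1 interval
  tandem <- c(p = paste0(paste(rep(unit, 5), collapse = ""),
                         random_dna(300, 0.4)))
  expect_identical(count_merged_hits(unit, tandem, min_length = 100L), 1L)
  # spaced copies count individually
  spaced <- c(p = paste0(paste0(vapply(1:5, function(i)
    paste0(random_dna(200, 0.4), unit), character(1)), collapse = ""),
    random_dna(300, 0.4)))
  expect_identical(count_merged_hits(unit, spaced, min_length = 100L), 5L)
})

test_that("raising thresholds never adds candidates", {
  es <- make_embedded_set(n_elem = 20, n_embed = 12, seed = 117)
  cand <- self_cluster(es$seqs)
  set.seed(118)
  peri <- c(p1 = paste0(paste0(vapply(1:15, function(i)
    paste0(random_dna(100, 0.4), es$unit), character(1)), collapse = ""),
    random_dna(400, 0.4)))
  n_kept <- vapply(list(c(5, 5), c(10, 5), c(12, 10), c(13, 15)),
                   function(th) nrow(filter_candidates(cand, peri,
                                                       min_self = th[1],
                                                       min_peri_hits = th[2])),
                   integer(1))
  expect_true(all(diff(n_kept) <= 0))
})

test_that("known-repeat exclusion flags identity down to diverged chimeras", {
  set.seed(119)
  probe <- random_dna(1000, 0.42)
  known <- c(kp = probe)
  mk_cand <- function(seqs) {
    d <- data.frame(unit_id = sprintf("u%d", seq_along(seqs)), seq = seqs,
                    length = nchar(seqs), self_occurrences = 60L,
                    rep_element = "x", rep_start = 0L,
                    rep_end = nchar(seqs), score = 100L)
    class(d) <- c("candidate_repeats", "data.frame")
    d
  }
  # identical to the probe: flagged and excluded
  same <- filter_known(mk_cand(substr(probe, 1, 600)), known)
  expect_identical(nrow(same), 0L)
  # unrelated: retained
  other <- filter_known(mk_cand(random_dna(600, 0.45)), known)
  expect_identical(nrow(other), 1L)
  expect_false(other$known_overlap)
  # chimera sharing a ~60% identity, 150 bp segment with the probe: flagged
  seg <- mutate_sequence(substr(probe, 301, 450), 0.6)  # ~40% divergence
  ident <- 1 - mean(strsplit(seg, "")[[1]] !=
                    strsplit(substr(probe, 301, 450), "")[[1]])
  expect_gt(ident, 0.55)
  chim <- paste0(random_dna(250, 0.45), seg, random_dna(250, 0.45))
  flagged <- filter_known(mk_cand(chim), known)
  expect_identical(nrow(flagged), 0L)
})

test_that("the full pipeline recovers a planted hidden repeat end-to-end", {
  sim <- simulate_chromosome(discovery_config(seed = 120))
  el <- sim$truth$elements
  peri_el <- el[el$compartment == "pericentromere", ]
  el_seqs <- setNames(substring(sim$seq, peri_el$start + 1, peri_el$end),
                      peri_el$id)
  rg <- sim$truth$regions
  peri_rg <- rg[rg$role == "pericentromere", ]
  peri_seqs <- setNames(substring(sim$seq, peri_rg$start + 1, peri_rg$end),
                        c("p1", "p2"))
  known <- setNames(sim$truth$probes$seq[sim$truth$probes$role ==
                                         "pericentromeric"], c("k1", "k2"))
  novel <- discover_repeats(el_seqs, peri_seqs, known)
  expect_identical(nrow(novel), 1L)
  expect_gt(novel$peri_hits, 1000L)
  h <- local_align(novel$seq, sim$truth$hidden_seq, min_identity = 0.8,
                   min_length = 100)
  expect_gte(max(h$aligned_columns) / nchar(sim$truth$hidden_seq), 0.95)
  f <- tempfile()
  write_candidates(novel, f)
  expect_true(file.exists(paste0(f, ".fa")))
  expect_true(file.exists(paste0(f, ".tsv")))
})
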
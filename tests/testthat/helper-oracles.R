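# Independent alignment oracles (Biostrings dynamic programming) and small
# construction helpers shared across tests.

sub_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                    baseOnly = TRUE)

# best local alignment by full Smith-Waterman; gap of length L costs 3+(L-1)
oracle_local <- function(q, t) {
  pa <- Biostrings::pairwiseAlignment(q, t, substitutionMatrix = sub_mat,
                                      gapOpening = 2, gapExtension = 1,
                                      type = "local")
  ap <- as.character(Biostrings::alignedPattern(pa))
  as <- as.character(Biostrings::alignedSubject(pa))
  cols <- nchar(ap)
  matches <- sum(strsplit(ap, "")[[1]] == strsplit(as, "")[[1]])
  list(score = Biostrings::score(pa),
       qstart = BiocGenerics::start(Biostrings::pattern(pa)) - 1L,
       qend = BiocGenerics::end(Biostrings::pattern(pa)),
       tstart = BiocGenerics::start(Biostrings::subject(pa)) - 1L,
       tend = BiocGenerics::end(Biostrings::subject(pa)),
       identity = matches / cols)
}

# unbanded global alignment oracle
oracle_global <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = sub_mat,
                                      gapOpening = 2, gapExtension = 1,
                                      type = "global")
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  list(score = Biostrings::score(pa),
       identity = sum(ap == as_) / length(ap),
       columns = length(ap))
}

# mutated-copy instance: target with a diverged copy of a query planted at a
# known position; optional small indels spliced into the copy
planted_instance <- function(tlen = 1500, qlen = 300, K = 0.05,
                             n_indel = 0, seed = 1) {
  set.seed(seed)
  q <- random_dna(qlen, 0.5)
  copy <- mutate_sequence(q, K)
  if (n_indel > 0) {
    for (z in seq_len(n_indel)) {
      pos <- sample(seq(20, nchar(copy) - 20), 1)
      if (runif(1) < 0.5) {   # deletion of 1-3 bp
        d <- sample(1:3, 1)
        copy <- paste0(substr(copy, 1, pos), substr(copy, pos + d + 1,
                                                    nchar(copy)))
      } else {                # insertion of 1-3 bp
        ins <- random_dna(sample(1:3, 1), 0.5)
        copy <- paste0(substr(copy, 1, pos), ins,
                       substr(copy, pos + 1, nchar(copy)))
      }
    }
  }
  at <- sample(seq(0, tlen - nchar(copy)), 1)
  t <- paste0(random_dna(at, 0.5), copy,
              random_dna(tlen - at - nchar(copy), 0.5))
  list(query = q, target = t, at = at, copy_len = nchar(copy))
}

# a dated two-LTR element on its own mini-chromosome, for dating tests
make_dated_element <- function(ltr_len = 1000, age_mya = 1, mu = 1.5e-8,
                               internal_len = 500) {
  ltr <- random_dna(ltr_len, 0.42)
  K <- mu * age_mya * 1e6
  l5 <- mutate_sequence(ltr, K)
  l3 <- mutate_sequence(ltr, K)
  internal <- random_dna(internal_len, 0.42)
  seqs <- paste0(l5, internal, l3)
  L <- nchar(seqs)
  list(seq = seqs,
       element = data.frame(id = "e1", chrom = "c", start = 0L, end = L,
                            ltr5_start = 0L, ltr5_end = ltr_len,
                            ltr3_start = L - ltr_len, ltr3_end = L,
                            family = "ALE", superfamily = "Copia",
                            stringsAsFactors = FALSE))
}

# per-base brute-force coverage oracle
oracle_coverage <- function(regions, features, universe) {
  rmask <- logical(universe); fmask <- logical(universe)
  for (i in seq_len(nrow(regions)))
    rmask[seq(regions$start[i] + 1, regions$end[i])] <- TRUE
  for (i in seq_len(nrow(features)))
    fmask[seq(features$start[i] + 1, features$end[i])] <- TRUE
  sum(rmask & fmask) / sum(rmask)
}

# DAG check: repeated leaf-stripping terminates iff the relation is acyclic
is_acyclic <- function(pairs) {
  edges <- pairs[, c("parent_id", "child_id")]
  nodes <- unique(unlist(edges))
  while (length(nodes) > 0) {
    leaves <- setdiff(nodes, edges$parent_id)
    if (length(leaves) == 0) return(FALSE)
    nodes <- setdiff(nodes, leaves)
    edges <- edges[!(edges$child_id %in% leaves), , drop = FALSE]
  }
  TRUE
}

# permutation two-sample test oracle for the mean difference
oracle_permutation_p <- function(a, b, n_perm = 1e4, seed = 1) {
  set.seed(seed)
  obs <- mean(a) - mean(b)
  pool <- c(a, b); na <- length(a)
  more <- replicate(n_perm, {
    p <- sample(pool)
    abs(mean(p[1:na]) - mean(p[-(1:na)])) >= abs(obs)
  })
  (sum(more) + 1) / (n_perm + 1)
}
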
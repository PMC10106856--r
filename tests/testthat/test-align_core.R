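# Alignment and distance primitives.

test_that("JC69 distance matches the closed form and its properties", {
  expect_identical(jc69_distance(0), 0)
  expect_equal(jc69_distance(0.10), -0.75 * log(1 - 0.4 / 3))
  expect_equal(jc69_distance(0.10), 0.107326, tolerance = 1e-5)
  p <- seq(0.01, 0.7, by = 0.01)
  K <- jc69_distance(p)
  expect_true(all(diff(K) > 0))       # strictly increasing
  expect_true(all(K >= p))            # correction never shrinks
  expect_error(jc69_distance(0.75), "saturation")
  expect_error(jc69_distance(-0.1), "nonnegative")
})

test_that("K2P distance matches the closed form and dominates JC69", {
  expect_identical(k2p_distance(0, 0), 0)
  expect_equal(k2p_distance(0.05, 0.05),
               -0.5 * log(0.85) - 0.25 * log(0.90))
  expect_error(k2p_distance(0.5, 0.2), "saturation")
  # transition-biased inputs: K2P >= JC69 at the same total mismatch
  for (ptot in seq(0.05, 0.4, by = 0.05)) {
    p <- 0.8 * ptot; q <- 0.2 * ptot
    expect_gte(k2p_distance(p, q), jc69_distance(ptot))
  }
})

test_that("global identity is exact on equal input and calibrated on JC pairs", {
  a <- random_dna(2000, 0.5, seed = 11)
  g <- global_identity(a, a)
  expect_identical(g$identity, 1)
  expect_identical(g$gap_columns, 0L)
  # a vs mutated copy at K = 0.05: expected identity 1 - p(K)
  ident <- vapply(1:8, function(s) {
    b <- mutate_sequence(a, 0.05, seed = 100 + s)
    global_identity(a, b)$identity
  }, numeric(1))
  p <- jc69_p_expected(0.05)
  se <- sqrt(p * (1 - p) / 2000)
  expect_lt(abs(mean(ident) - (1 - p)), 3 * se)
})

test_that("banded global agrees with the unbanded DP oracle", {
  for (s in 1:10) {
    set.seed(s)
    n <- sample(100:1000, 1)
    a <- random_dna(n, 0.5)
    b <- mutate_sequence(a, runif(1, 0, 0.1))
    # splice a small indel into half the cases
    if (s %% 2 == 0) {
      pos <- sample(seq(10, nchar(b) - 10), 1)
      b <- paste0(substr(b, 1, pos), substr(b, pos + 3, nchar(b)))
    }
    g <- global_identity(a, b, band = 50)
    o <- oracle_global(a, b)
    expect_identical(g$score, as.integer(o$score))
    expect_equal(g$identity, o$identity, tolerance = 1e-9)
  }
})

test_that("infeasible band is rejected", {
  a <- random_dna(500, 0.5, seed = 1)
  b <- random_dna(600, 0.5, seed = 2)
  expect_error(global_identity(a, b, band = 50), "infeasible-band")
})

test_that("local alignment finds exact substrings with identity 1", {
  t <- random_dna(5000, 0.5, seed = 21)
  q <- substr(t, 2001, 2300)
  h <- local_align(q, t, min_identity = 0.9, min_length = 50)
  top <- h[which.max(h$score), ]
  expect_identical(top$identity, 1)
  expect_identical(top$tstart, 2000L)
  expect_identical(top$tend, 2300L)
  expect_identical(top$strand, "+")
})

test_that("absent query yields no hits on random targets", {
  set.seed(5)
  for (s in 1:5) {
    t <- random_dna(10000, 0.5)
    q <- random_dna(100, 0.5)
    h <- local_align(q, t, min_identity = 0.9, min_length = 50)
    expect_identical(nrow(h), 0L)
  }
})

test_that("local alignment equals the Smith-Waterman oracle on planted instances", {
  for (s in 1:30) {
    inst <- planted_instance(tlen = sample(500:2000, 1),
                             qlen = sample(100:400, 1),
                             K = runif(1, 0, 0.08),
                             n_indel = s %% 3, seed = 1000 + s)
    h <- local_align(inst$query, inst$target, min_identity = 0.8,
                     min_length = 50)
    expect_gt(nrow(h), 0)
    top <- h[which.max(h$score), ]
    o <- oracle_local(inst$query, inst$target)
    expect_identical(top$score, as.integer(o$score))
    # equal-scoring optima can differ by a few tie-broken edge columns
    expect_lte(abs(top$qstart - o$qstart), 10)
    expect_lte(abs(top$qend - o$qend), 10)
    expect_lte(abs(top$tstart - o$tstart), 10)
    expect_lte(abs(top$tend - o$tend), 10)
    expect_equal(top$identity, o$identity, tolerance = 0.02)
  }
})

test_that("strand symmetry: reverse-complemented queries flip the strand label", {
  inst <- planted_instance(seed = 7, K = 0.03)
  h_fwd <- local_align(inst$query, inst$target, min_length = 50)
  h_rev <- local_align(revcomp(inst$query), inst$target, min_length = 50)
  expect_identical(nrow(h_fwd), nrow(h_rev))
  f <- h_fwd[order(h_fwd$tstart), ]
  r <- h_rev[order(h_rev$tstart), ]
  expect_identical(f$tstart, r$tstart)
  expect_identical(f$tend, r$tend)
  expect_identical(f$score, r$score)
  expect_true(all(f$strand != r$strand))
})

test_that("mutate_sequence realises the JC69 marginal", {
  s <- random_dna(50000, 0.4, seed = 31)
  expect_identical(mutate_sequence(s, 0), s)
  expect_error(mutate_sequence("ACGTN", 0.1), "non-ACGT")
  m <- mutate_sequence(s, 0.03, seed = 32)
  expect_identical(nchar(m), nchar(s))
  p_hat <- mean(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
  p <- jc69_p_expected(0.03)
  expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / 50000))
  # two independent branches of K compose to 2K
  c1 <- mutate_sequence(s, 0.03, seed = 33)
  c2 <- mutate_sequence(s, 0.03, seed = 34)
  p2_hat <- mean(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  p2 <- jc69_p_expected(0.06)
  expect_lt(abs(p2_hat - p2), 3 * sqrt(p2 * (1 - p2) / 50000))
})

test_that("hit tables round-trip to outfmt6-like TSV and BED", {
  inst <- planted_instance(seed = 9)
  h <- local_align(inst$query, inst$target, min_length = 50)
  f <- tempfile(fileext = ".tsv")
  write_hits_tsv(h, f)
  back <- read.table(f, header = TRUE, sep = "\t")
  expect_identical(nrow(back), nrow(h))
  expect_identical(back$tstart, h$tstart)
  fb <- tempfile(fileext = ".bed")
  write_bed(data.frame(chrom = h$target_id, start = h$tstart, end = h$tend),
            fb)
  bed <- read.table(fb, sep = "\t")
  expect_identical(bed$V2, h$tstart)
})
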
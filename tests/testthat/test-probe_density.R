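# Probe mapping, windowed density tracks and telomere screening.

test_that("an exactly tiled monomer is recovered at identity 1 covering the array", {
  mono <- random_dna(176, 0.42, seed = 51)
  arr <- paste(rep(mono, 50), collapse = "")
  genome <- c(chr1 = paste0(random_dna(5000, 0.4, seed = 52), arr,
                            random_dna(5000, 0.4, seed = 53)))
  probes <- probe_set(centromeric = c(cent1 = mono))
  hits <- map_probes(genome, probes)
  expect_gte(nrow(hits), 50)
  expect_true(all(hits$identity >= 0.99))
  red <- centroscape:::reduce_intervals(hits$tstart, hits$tend)
  covered <- sum(red$end - red$start)
  expect_gte(covered, 50 * 176 - 176)   # whole array up to edge fragments
})

test_that("diverged copies (K = 0.1) are recalled at >= 95%", {
  set.seed(54)
  mono <- random_dna(176, 0.42)
  n <- 100
  copies <- vapply(1:n, function(i) mutate_sequence(mono, 0.1), character(1))
  spacers <- vapply(1:n, function(i) random_dna(60, 0.4), character(1))
  genome <- c(chr1 = paste0(paste0(spacers, copies, collapse = ""),
                            random_dna(2000, 0.4)))
  starts <- cumsum(c(0, rep(236, n - 1))) + 60
  hits <- map_probes(genome, probe_set(centromeric = c(m = mono)),
                     min_identity = 0.8)
  recalled <- vapply(starts, function(s) {
    any(pmin(hits$tend, s + 176) - pmax(hits$tstart, s) >= 0.5 * 176)
  }, logical(1))
  expect_gte(mean(recalled), 0.95)
})

test_that("arm-only sequence yields near-zero centromeric probe coverage", {
  arm <- c(chr1 = random_dna(3e5, 0.36, seed = 55))
  mono <- random_dna(176, 0.42, seed = 56)
  hits <- map_probes(arm, probe_set(centromeric = c(m = mono)))
  covered <- if (nrow(hits) == 0) 0 else {
    red <- centroscape:::reduce_intervals(hits$tstart, hits$tend)
    sum(red$end - red$start)
  }
  expect_lt(covered / 3e5, 0.001)
})

test_that("window densities match a brute-force per-base oracle", {
  set.seed(57)
  for (rep in 1:10) {
    clen <- 50000
    nh <- sample(5:30, 1)
    st <- sort(sample(0:(clen - 500), nh))
    en <- pmin(st + sample(50:500, nh, replace = TRUE), clen)
    hits <- data.frame(query_id = "q", target_id = "chr1", qstart = 0L,
                       qend = 10L, tstart = st, tend = en, strand = "+",
                       matches = 1L, aligned_columns = 1L, gap_columns = 0L,
                       identity = 1, score = 1L, role = "centromeric")
    w <- 5000; s <- 1000
    tr <- density_track(hits, clen, w, s)
    mask <- logical(clen)
    for (i in seq_len(nh)) mask[(st[i] + 1):en[i]] <- TRUE
    expected <- vapply(seq_len(nrow(tr)), function(i)
      mean(mask[(tr$start[i] + 1):tr$end[i]]), numeric(1))
    expect_equal(tr$value, expected, tolerance = 1e-12)
  }
})

test_that("density extremes and invariants hold", {
  none <- data.frame(query_id = character(), target_id = character(),
                     qstart = integer(), qend = integer(),
                     tstart = integer(), tend = integer(),
                     strand = character(), matches = integer(),
                     aligned_columns = integer(), gap_columns = integer(),
                     identity = numeric(), score = integer())
  tr0 <- density_track(none, 1e6)
  expect_true(all(tr0$value == 0))
  full <- data.frame(query_id = "q", target_id = "chr1", qstart = 0L,
                     qend = 1L, tstart = 0L, tend = 1000000L, strand = "+",
                     matches = 1L, aligned_columns = 1L, gap_columns = 0L,
                     identity = 1, score = 1L)
  expect_true(all(density_track(full, 1e6)$value == 1))
  # splitting one hit into abutting pieces does not change any window
  one <- full; one$tend <- 600000L
  two <- rbind(one, one); two$tstart <- c(0L, 300000L); two$tend <- c(300000L, 600000L)
  expect_equal(density_track(one, 1e6)$value, density_track(two, 1e6)$value)
  # with step == window, value * width sums to total covered bp
  tr <- density_track(one, 1e6, window_size = 1e5, step = 1e5)
  expect_equal(sum(tr$value * (tr$end - tr$start)), 600000)
  expect_error(density_track(one, 1e6, window_size = 1e5, step = 2e5),
               "step")
})

test_that("telomere screening flags planted ends and not random ends", {
  motif <- "TTTAGGG"
  arr <- paste(rep(motif, 300), collapse = "")
  g <- c(yes = paste0(random_dna(20000, 0.36, seed = 58), arr),
         no = random_dna(22100, 0.36, seed = 59))
  tel <- detect_telomeres(g, motif)
  expect_true(tel$telomeric[tel$chrom == "yes" & tel$end == "right"])
  expect_false(tel$telomeric[tel$chrom == "yes" & tel$end == "left"])
  expect_false(any(tel$telomeric[tel$chrom == "no"]))
  expect_error(detect_telomeres(g, "TTTA"), "length")
})

test_that("a 10-chromosome genome with 18 planted telomeres yields exactly 18 calls", {
  g <- simulate_telomere_genome(seed = 60)
  tel <- detect_telomeres(g$seqs, "TTTAGGG", end_window = 5000)
  expect_identical(sum(tel$telomeric), 18L)
  merged <- merge(tel, g$truth, by = c("chrom", "end"))
  expect_identical(merged$telomeric, merged$planted)
})

test_that("bedGraph output round-trips window values", {
  hits <- data.frame(query_id = "q", target_id = "chr1", qstart = 0L,
                     qend = 1L, tstart = 1000L, tend = 21000L, strand = "+",
                     matches = 1L, aligned_columns = 1L, gap_columns = 0L,
                     identity = 1, score = 1L)
  tr <- density_track(hits, 1e5, 1e4, 5e3)
  f <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, f)
  back <- read.table(f, skip = 1, sep = "\t")
  expect_equal(back$V4, tr$value)
})
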
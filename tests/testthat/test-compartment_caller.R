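# Region calling from density tracks and compartment assignment.

mk_track <- function(values, window = 5e5, step = 1e5, chrom = "chr1") {
  n <- length(values)
  tr <- data.frame(chrom = rep(chrom, n), start = (seq_len(n) - 1) * step,
                   end = (seq_len(n) - 1) * step + window, value = values)
  attr(tr, "window_size") <- window
  attr(tr, "step") <- step
  class(tr) <- c("window_track", "data.frame")
  tr
}

test_that("an all-zero track yields no regions", {
  expect_identical(nrow(call_regions(mk_track(rep(0, 30)))), 0L)
  expect_error(call_regions(mk_track(numeric(0))), "empty")
})

test_that("two arrays separated by a wide zero gap give two regions", {
  v <- c(rep(0, 3), rep(0.5, 4), rep(0, 10), rep(0.5, 4), rep(0, 3))
  rg <- call_regions(mk_track(v), threshold = 0.1, min_run = 2, merge_gap = 2)
  expect_identical(nrow(rg), 2L)
  # a short gap is merged instead
  v2 <- c(rep(0, 3), rep(0.5, 4), rep(0, 2), rep(0.5, 4), rep(0, 3))
  rg2 <- call_regions(mk_track(v2), threshold = 0.1, min_run = 2, merge_gap = 2)
  expect_identical(nrow(rg2), 1L)
  # runs shorter than min_run are dropped
  v3 <- c(rep(0, 5), 0.5, rep(0, 10))
  expect_identical(nrow(call_regions(mk_track(v3), min_run = 2)), 0L)
})

test_that("region boundaries snap to outermost probe hits in the run", {
  v <- c(rep(0, 2), rep(0.4, 4), rep(0, 4))
  hits <- data.frame(tstart = c(234567L, 400000L), tend = c(300000L, 567890L))
  rg <- call_regions(mk_track(v), hits = hits)
  expect_identical(rg$start, 234567L)
  expect_identical(rg$end, 567890L)
})

test_that("raising the threshold never enlarges the called territory", {
  set.seed(71)
  union_bp <- function(rg) {
    if (nrow(rg) == 0) return(0)
    r <- IRanges::reduce(IRanges::IRanges(rg$start + 1L, rg$end))
    sum(BiocGenerics::width(r))
  }
  for (rep in 1:10) {
    v <- pmax(0, rnorm(40, 0.12, 0.1))
    tot <- vapply(c(0.05, 0.1, 0.2, 0.3), function(th)
      union_bp(call_regions(mk_track(v), threshold = th)), numeric(1))
    expect_true(all(diff(tot) <= 0))
  }
})

test_that("compartments are recovered on a small simulated chromosome", {
  cfg <- sim_config(chromosome_length = 1.5e6, cent_span = 3e5,
                    peri_span = 1.5e5,
                    n_ltr = list(centromere = c(ALE = 8, CRM = 4),
                                 pericentromere = c(Tekay = 5, CRM = 3),
                                 arm = c(Angela = 2)),
                    hidden_repeat = list(length = 300, n_peri = 60,
                                         n_embed = 6),
                    seed = 72)
  sim <- simulate_chromosome(cfg)
  hits <- map_probes(sim$seq, sim$truth$probes)
  regions <- call_compartments(hits, nchar(sim$seq[[1]]),
                               window_size = 2e5, step = 4e4)
  tc <- sim$truth$regions[sim$truth$regions$role == "centromere", ]
  cc <- regions[regions$role == "centromere", ]
  expect_identical(nrow(cc), 1L)
  expect_lte(abs(cc$start - tc$start), 4e4)
  expect_lte(abs(cc$end - tc$end), 4e4)
  # pericentromere calls flank the centromere and do not overlap it
  pc <- regions[regions$role == "pericentromere", ]
  expect_gte(nrow(pc), 2L)
  expect_true(all(pc$end <= cc$start | pc$start >= cc$end))
  # >= 95% of planted elements get their true compartment back
  el <- sim$truth$elements
  lab <- assign_compartments(el, regions)
  truth_lab <- ifelse(el$compartment == "arm", "non-(peri)centromere",
                      el$compartment)
  expect_gte(mean(lab == truth_lab), 0.95)

  # idempotence: re-calling on a track rebuilt from in-region hits only
  ch <- hits[hits$role == "centromeric", ]
  inrun <- ch[ch$tstart >= cc$start & ch$tend <= cc$end, ]
  tr2 <- density_track(inrun, nchar(sim$seq[[1]]), 2e5, 4e4)
  rg2 <- call_regions(tr2, hits = inrun, role = "centromere")
  expect_identical(rg2$start, cc$start)
  expect_identical(rg2$end, cc$end)
})

test_that("midpoint rule and precedence govern compartment assignment", {
  regions <- data.frame(chrom = "chr1",
                        start = c(100L, 150L), end = c(200L, 260L),
                        role = c("centromere", "pericentromere"),
                        evidence = 1)
  items <- data.frame(chrom = "chr1",
                      start = c(120L, 90L, 300L, 160L),
                      end = c(180L, 130L, 400L, 240L))
  lab <- assign_compartments(items, regions)
  expect_identical(lab[1], "centromere")
  # midpoint 110 inside centromere [100,200)
  expect_identical(lab[2], "centromere")
  expect_identical(lab[3], "non-(peri)centromere")
  # midpoint 200: outside centromere (half-open), inside pericentromere
  expect_identical(lab[4], "pericentromere")
  expect_error(assign_compartments(items, regions, chrom_length = 350),
               "bounds")
})

test_that("region BED output carries the role and a parameter sidecar", {
  v <- c(rep(0, 2), rep(0.4, 4), rep(0, 4))
  rg <- call_regions(mk_track(v), role = "centromere")
  f <- tempfile(fileext = ".bed")
  write_regions_bed(rg, f)
  bed <- read.table(f, sep = "\t")
  expect_identical(bed$V4, "centromere")
  expect_true(file.exists(paste0(f, ".params.json")))
  p <- jsonlite::read_json(paste0(f, ".params.json"))
  expect_identical(p$threshold, 0.1)
})
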
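# LTR dating, age classification, nested insertions and composition.

test_that("GFF3 coordinates convert to 0-based half-open and round-trip", {
  gff <- c("##gff-version 3",
           "chr1\tx\tLTR_retrotransposon\t1001\t6000\t.\t+\t.\tID=e1;family=ALE;superfamily=Copia",
           "chr1\tx\tlong_terminal_repeat\t1001\t1500\t.\t+\t.\tID=e1_l5;Parent=e1",
           "chr1\tx\tlong_terminal_repeat\t5501\t6000\t.\t+\t.\tID=e1_l3;Parent=e1",
           "chr1\tx\tLTR_retrotransposon\t8001\t9000\t.\t+\t.\tID=e2",
           "chr1\tx\tlong_terminal_repeat\t8001\t8100\t.\t+\t.\tID=e2_l5;Parent=e2")
  f <- tempfile(fileext = ".gff3")
  writeLines(gff, f)
  expect_warning(read_ltr_annotations(f), "lacks two LTR")
  el <- suppressWarnings(read_ltr_annotations(f))
  expect_identical(nrow(el), 1L)
  expect_identical(attr(el, "skipped"), 1L)
  expect_identical(el$start, 1000L)
  expect_identical(el$end, 6000L)
  expect_identical(el$ltr5_end, 1500L)
  expect_identical(el$family, "ALE")
  f2 <- tempfile(fileext = ".gff3")
  write_ltr_gff3(el, f2)
  back <- read_ltr_annotations(f2)
  expect_identical(back$start, el$start)
  expect_identical(back$ltr3_start, el$ltr3_start)
  expect_identical(back$family, el$family)
})

test_that("identical LTR copies date to age zero", {
  e <- make_dated_element(age_mya = 0)
  dated <- estimate_age(e$element, c(c = e$seq))
  expect_identical(dated$p_obs, 0)
  expect_identical(dated$age_mya, 0)
  expect_identical(dated$age_class, "young")
})

test_that("age arithmetic follows T = K / (2 mu)", {
  # LTR pair with a known mismatch count: p_obs chosen so K ~ 0.03
  set.seed(81)
  L <- 10000L
  ltr <- random_dna(L, 0.42)
  p_target <- jc69_p_expected(0.03)     # fraction giving exactly K = 0.03
  d <- round(L * p_target)
  pos <- sample(L, d)
  chars <- strsplit(ltr, "")[[1]]
  flip <- c(A = "C", C = "G", G = "T", T = "A")
  chars[pos] <- flip[chars[pos]]
  ltr3 <- paste(chars, collapse = "")
  seqs <- paste0(ltr, random_dna(200, 0.42), ltr3)
  el <- data.frame(id = "e", chrom = "c", start = 0L, end = nchar(seqs),
                   ltr5_start = 0L, ltr5_end = L,
                   ltr3_start = nchar(seqs) - L, ltr3_end = nchar(seqs),
                   family = "ALE", superfamily = "Copia")
  dated <- estimate_age(el, c(c = seqs), mu = 1.5e-8)
  expect_equal(dated$p_obs, d / L, tolerance = 1e-9)
  expect_equal(dated$age_mya, jc69_distance(d / L) / (2 * 1.5e-8) / 1e6,
               tolerance = 1e-9)
  expect_equal(dated$age_mya, 1.0, tolerance = 0.01)
})

test_that("dating recovers planted ages across a uniform range", {
  set.seed(83)
  ages <- runif(50, 0, 2)
  items <- lapply(ages, function(a) make_dated_element(1000, a))
  genome <- setNames(vapply(items, `[[`, "", "seq"), sprintf("c%03d", 1:50))
  el <- do.call(rbind, lapply(seq_along(items), function(i) {
    d <- items[[i]]$element; d$chrom <- names(genome)[i]; d
  }))
  dated <- estimate_age(el, genome)
  # binomial sampling over 1 kb alignments bounds the achievable precision:
  # the expected MAE at these conditions is ~0.14 MYA
  expect_gte(cor(ages, dated$age_mya), 0.9)
  expect_lte(mean(abs(ages - dated$age_mya)), 0.2)
  expect_lt(abs(mean(dated$age_mya - ages)), 0.1)   # no systematic bias
})

test_that("young/old classification uses a closed boundary at the threshold", {
  expect_identical(classify_age(0.5), "young")
  expect_identical(classify_age(0.5 + 1e-6), "old")
  expect_identical(classify_age(0), "young")
  expect_identical(classify_age(c(0.1, 0.9)), c("young", "old"))
  expect_error(classify_age(Inf), "finite")
})

test_that("nested detection emits strict containment pairs with age checks", {
  el <- data.frame(id = c("A", "B", "C"), chrom = "c",
                   start = c(0L, 100L, 1000L), end = c(500L, 300L, 1200L),
                   age_mya = c(1.0, 0.2, 0.5))
  nd <- detect_nested(el)
  expect_identical(nrow(nd), 1L)
  expect_identical(nd$parent_id, "A")
  expect_identical(nd$child_id, "B")
  expect_true(nd$consistent)
  # an older child is flagged inconsistent
  el$age_mya[2] <- 2.0
  expect_false(detect_nested(el)$consistent)
  # disjoint elements give nothing
  expect_identical(nrow(detect_nested(el[c(1, 3), ])), 0L)
})

test_that("planted nests are recovered exactly and the relation is acyclic", {
  cfg <- sim_config(chromosome_length = 1.2e6, cent_span = 2.5e5,
                    peri_span = 1.2e5,
                    n_ltr = list(centromere = c(ALE = 15, CRM = 10),
                                 pericentromere = c(Tekay = 10, CRM = 5),
                                 arm = c(Angela = 4)),
                    nested_fraction = 0.25,
                    hidden_repeat = NULL, seed = 84)
  sim <- simulate_chromosome(cfg)
  el <- sim$truth$elements
  nd <- detect_nested(el)
  got <- sort(paste(nd$parent_id, nd$child_id))
  want <- sort(paste(sim$truth$nested_pairs$parent_id,
                     sim$truth$nested_pairs$child_id))
  expect_gt(length(want), 0)
  expect_identical(got, want)
  # antisymmetric and acyclic
  expect_false(any(paste(nd$child_id, nd$parent_id) %in%
                   paste(nd$parent_id, nd$child_id)))
  expect_true(is_acyclic(nd))
})

test_that("composition tables are exhaustive and normalised", {
  el <- data.frame(id = sprintf("e%d", 1:40),
                   compartment = rep(c("centromere", "pericentromere"),
                                     c(30, 10)),
                   family = rep(c("ALE", "CRM", "Tekay"), c(25, 10, 5)),
                   superfamily = rep(c("Copia", "Gypsy"), c(25, 15)),
                   age_mya = runif(40, 0, 1), reliable = TRUE)
  tab <- composition_table(el, "family")
  expect_identical(tab$n[tab$compartment == "centromere" & tab$group == "ALE"],
                   25L)
  tot <- tapply(tab$percent, tab$compartment, sum)
  expect_equal(as.numeric(tot), c(100, 100))
  expect_identical(sum(tab$n), 40L)
  sup <- composition_table(el, "superfamily")
  expect_equal(sum(sup$percent[sup$compartment == "centromere"]), 100)
})

test_that("the structural finder locates young planted elements", {
  cfg <- sim_config(chromosome_length = 8e5, cent_span = 1.5e5,
                    peri_span = 8e4,
                    n_ltr = list(centromere = c(ALE = 6, CRM = 3),
                                 pericentromere = c(Tekay = 3),
                                 arm = c(Angela = 2)),
                    hidden_repeat = NULL, seed = 85)
  sim <- simulate_chromosome(cfg)
  fl <- find_ltr_elements(sim$seq)
  tru <- sim$truth$elements
  matched <- vapply(seq_len(nrow(tru)), function(i)
    any(abs(fl$start - tru$start[i]) < 10 & abs(fl$end - tru$end[i]) < 10),
    logical(1))
  expect_gte(mean(matched), 0.7)
})
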
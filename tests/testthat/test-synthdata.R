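# Generators: consensus drawing, per-copy mutation, genome construction,
# read simulation, RNA-seq simulation.

test_that("make_consensus honours length, composition and determinism", {
  expect_error(make_consensus(3), "length")

  x <- make_consensus(4, at_content = 1.0, seed = 1)
  expect_match(x, "^[AT]{4}$")

  y <- make_consensus(165, at_content = 0.72, seed = 7)
  expect_equal(nchar(y), 165)
  # observed A+T within the binomial 99% CI of 0.72 at n = 165
  half <- 2.576 * sqrt(0.72 * 0.28 / 165)
  at <- nchar(gsub("[CG]", "", y)) / 165
  expect_gt(at, 0.72 - half)
  expect_lt(at, 0.72 + half)

  expect_identical(y, make_consensus(165, at_content = 0.72, seed = 7))
})

test_that("mutate_copy matches its substitution model in the large-sample limit", {
  mono <- make_consensus(165, 0.65, 3)
  expect_identical(mutate_copy(mono, 0, indel_rate = 0, seed = 1), mono)

  set.seed(11)
  n <- 10000
  copies <- vapply(seq_len(n), function(i) mutate_copy(mono, 0.05), character(1))
  mref <- strsplit(mono, "")[[1]]
  pdist <- vapply(copies, function(cp) mean(strsplit(cp, "")[[1]] != mref), 1)
  sites <- n * 165
  half <- 2.576 * sqrt(0.05 * 0.95 / sites)
  expect_lt(abs(mean(pdist) - 0.05), half * 1.5)

  # pooled transition fraction at ts_tv_ratio = 2 is 2/3, within its 99% CI
  set.seed(12)
  copies2 <- vapply(seq_len(n), function(i) mutate_copy(mono, 0.1, ts_tv_ratio = 2),
                    character(1))
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  ts <- 0; tv <- 0
  for (cp in copies2) {
    cc <- strsplit(cp, "")[[1]]
    diff <- cc != mref
    same_class <- purine[cc] == purine[mref]
    ts <- ts + sum(diff & same_class)
    tv <- tv + sum(diff & !same_class)
  }
  p_hat <- ts / (ts + tv)
  half <- 2.576 * sqrt((2 / 3) * (1 / 3) / (ts + tv))
  expect_lt(abs(p_hat - 2 / 3), half * 1.5)
  expect_lt(abs(ts / tv - 2), 0.12)
})

test_that("build_genome plants arrays matching the target proportion", {
  spec <- sat_family_spec("f", make_consensus(100, 0.6, 1),
                          target_proportion = 0.02, divergence = 0.05)
  g <- build_genome(spec, 1e6, seed = 2)
  expect_gte(g$families$proportion, 0.0195)
  expect_lte(g$families$proportion, 0.0205)
  expect_equal(sum(nchar(g$genome$seq)), 1e6)
  # conservation: truth interval lengths define the realized fraction exactly
  expect_equal(sum(g$arrays$end - g$arrays$start) / 1e6, g$families$proportion)
})

test_that("build_genome with no families returns pure background", {
  g <- build_genome(sat_family_spec(character(), character(), numeric(),
                                    numeric())[0, ], 5e4, seed = 1)
  expect_equal(nrow(g$arrays), 0)
  expect_equal(nchar(g$genome$seq), 5e4)
})

test_that("subfamily arrays never mix variants", {
  monoA <- make_consensus(90, 0.65, 5)
  monoB <- mutate_copy(monoA, 0.12, seed = 6)
  specs <- dplyr::bind_rows(
    sat_family_spec("fam.A", monoA, 0.01, 0.02, n_arrays = 5, subfamily_of = "fam"),
    sat_family_spec("fam.B", monoB, 0.01, 0.02, n_arrays = 5, subfamily_of = "fam"))
  g <- build_genome(specs, 5e5, seed = 7)
  expect_equal(nrow(g$arrays), 10)
  # each truth interval is labelled with exactly one variant, and its
  # sequence matches that variant far better than the other
  gen <- g$genome$seq
  for (i in seq_len(nrow(g$arrays))) {
    arr <- substr(gen, g$arrays$start[i] + 1, g$arrays$start[i] + 90)
    dA <- satkit:::rotation_distance(arr, monoA)
    dB <- satkit:::rotation_distance(arr, monoB)
    own_is_A <- g$arrays$family[i] == "fam.A"
    expect_true(if (own_is_A) dA < dB else dB < dA)
  }
})

test_that("sim_reads produces the documented pair count and exact substrings", {
  g <- build_genome(sat_family_spec("f", make_consensus(80, 0.6, 1), 0.01, 0.01),
                    1e6, seed = 3)
  rd <- sim_reads(g, coverage = 0.5, seed = 4)
  expect_equal(nrow(rd) / 2, 1667)  # ceiling(0.5e6 / 300)

  rd0 <- sim_reads(g, coverage = 0.05, error_rate = 0, seed = 5)
  gen <- g$genome$seq
  ok <- vapply(rd0$seq, function(s) {
    grepl(s, gen, fixed = TRUE) || grepl(revcomp(s), gen, fixed = TRUE)
  }, logical(1))
  expect_true(all(ok))

  expect_identical(sim_reads(g, coverage = 0.1, seed = 9),
                   sim_reads(g, coverage = 0.1, seed = 9))
  expect_error(sim_reads(tibble::tibble(id = "s", seq = strrep("A", 100)),
                         coverage = 1), "insert")
})

test_that("assembly pseudo-reads cover scaffolds proportionally to length", {
  asm <- tibble::tibble(id = "s1", seq = satkit:::random_dna(10000, 0.5))
  pr <- assembly_pseudo_reads(asm, coverage = 1, seed = 1)
  expect_equal(nrow(pr) / 2, 34)  # ceiling(10000 / 300)

  set.seed(2)
  asm2 <- tibble::tibble(id = c("big", "small"),
                         seq = c(satkit:::random_dna(90000, 0.5),
                                 satkit:::random_dna(10000, 0.5)))
  pr2 <- assembly_pseudo_reads(asm2, coverage = 3, seed = 3)
  m1 <- pr2[pr2$mate == 1, ]
  n_pairs <- nrow(m1)
  n_big <- sum(vapply(m1$seq, function(s) {
    grepl(s, asm2$seq[1], fixed = TRUE) ||
      grepl(revcomp(s), asm2$seq[1], fixed = TRUE)
  }, logical(1)))
  # multinomial 99% CI around p = 0.9 (usable-length share of the big scaffold)
  p <- (90000 - 299) / (90000 - 299 + 10000 - 299)
  half <- 2.576 * sqrt(p * (1 - p) / n_pairs)
  expect_lt(abs(n_big / n_pairs - p), half * 1.5)

  expect_error(assembly_pseudo_reads(tibble::tibble(id = character(),
                                                    seq = character()), 1),
               "empty")
  expect_warning(assembly_pseudo_reads(
    tibble::tibble(id = c("ok", "tiny"),
                   seq = c(satkit:::random_dna(5000, 0.5), "ACGT")), 0.5),
    "Skipping")
})

test_that("sim_rnaseq draws family reads with the planted expectations", {
  fams <- tibble::tibble(
    name = c("A", "B"),
    reference = c(build_reference(make_consensus(100, 0.6, 1)),
                  build_reference(make_consensus(150, 0.6, 2))))
  rna <- sim_rnaseq(fams, c(A = 1, B = 0), background_fraction = 0.9,
                    library_size = 100000, seed = 1)
  nA <- sum(rna$origin == "A")
  half <- 2.576 * sqrt(100000 * 0.1 * 0.9)
  expect_lt(abs(nA - 10000), half * 1.5)
  expect_equal(sum(rna$origin == "B"), 0)

  expect_identical(sim_rnaseq(fams, c(A = 2, B = 1), 0.5, 1000, seed = 3),
                   sim_rnaseq(fams, c(A = 2, B = 1), 0.5, 1000, seed = 3))
  expect_error(sim_rnaseq(fams, c(A = 0, B = 0), 0, 1000), "zero")
})
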
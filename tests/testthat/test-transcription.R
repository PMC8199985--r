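# RNA-seq counting, CPM normalization, expression filtering, pattern
# classification and the abundance correlation.

test_that("count_rna_reads assigns each read to its best family", {
  refA <- build_reference(make_consensus(120, 0.6, 41))
  refB <- build_reference(make_consensus(150, 0.6, 42))
  refs <- tibble::tibble(family = c("A", "B"), reference = c(refA, refB))

  rna <- sim_rnaseq(tibble::tibble(name = c("A", "B"),
                                   reference = c(refA, refB)),
                    c(A = 1, B = 0), background_fraction = 0,
                    library_size = 100, seed = 1)
  cnt <- count_rna_reads(rna, refs)
  expect_equal(cnt$count[cnt$family == "A"], 100)
  expect_equal(cnt$count[cnt$family == "B"], 0)
  expect_equal(sum(cnt$count), 100)

  # a read matching two identical references ties to the first name
  refs_tie <- tibble::tibble(family = c("zeta", "alpha"),
                             reference = c(refA, refA))
  read <- tibble::tibble(id = "r", seq = substr(refA, 1, 150))
  cnt_tie <- count_rna_reads(read, refs_tie)
  expect_equal(cnt_tie$count[cnt_tie$family == "alpha"], 1)
  expect_equal(cnt_tie$count[cnt_tie$family == "zeta"], 0)

  expect_error(count_rna_reads(read[0, ], refs), "empty")
})

test_that("planted 3:1 expression weights recover in the counts", {
  refA <- build_reference(make_consensus(120, 0.6, 43))
  refB <- build_reference(make_consensus(100, 0.6, 44))
  fams <- tibble::tibble(name = c("A", "B"), reference = c(refA, refB))
  rna <- sim_rnaseq(fams, c(A = 3, B = 1), background_fraction = 0.4,
                    library_size = 8000, seed = 2)
  cnt <- count_rna_reads(rna, dplyr::rename(fams, family = name))
  nA <- cnt$count[cnt$family == "A"]
  nB <- cnt$count[cnt$family == "B"]
  p_hat <- nA / (nA + nB)
  half <- 2.576 * sqrt(0.75 * 0.25 / (nA + nB))
  expect_lt(abs(p_hat - 0.75), half * 1.5)
})

test_that("CPM normalization conserves a million per sample", {
  cpm <- cpm_normalize(tibble::tibble(family = c("a", "bg"),
                                      s1 = c(75L, 1499925L)))
  expect_equal(cpm$s1[1], 50)
  expect_equal(sum(cpm$s1), 1e6)

  # scale-invariance: doubling all counts leaves CPM unchanged
  x <- tibble::tibble(family = c("a", "b"), s1 = c(10L, 90L))
  expect_equal(cpm_normalize(x)$s1,
               cpm_normalize(dplyr::mutate(x, s1 = s1 * 2L))$s1)

  expect_error(cpm_normalize(tibble::tibble(family = "a", s1 = 0L)),
               "positive")
})

test_that("the expression filter is strictly >50 CPM in >=2 samples", {
  cpm <- tibble::tibble(
    family = c("kept", "one_sample", "boundary"),
    s1 = c(60, 60, 50), s2 = c(55, 49, 50), s3 = c(0, 49, 50),
    s4 = c(0, 49, 50), s5 = c(0, 49, 50))
  flt <- filter_expressed(cpm)
  expect_equal(flt$retained, c(TRUE, FALSE, FALSE))

  # idempotent: filtering the filtered set changes nothing
  again <- filter_expressed(dplyr::select(flt, -retained))
  expect_equal(again$retained, flt$retained)
})

test_that("pattern classification uses the dominance threshold", {
  expect_equal(classify_pattern(100, 100, 100), "P1")
  expect_equal(classify_pattern(900, 10, 10), "P2")
  expect_equal(classify_pattern(10, 450, 450), "P3")
  expect_equal(classify_pattern(10, 900, 5), "P4")
  expect_true(is.na(classify_pattern(0, 0, 0)))
  # scale-invariance
  expect_equal(classify_pattern(10, 450, 450), classify_pattern(1, 45, 45))
  expect_error(classify_pattern(-1, 0, 1), ">= 0")
})

test_that("correlate_abundance matches the rank formula and tie handling", {
  up <- correlate_abundance(c(1, 2, 3, 5, 8, 13), c(2, 4, 8, 16, 32, 64))
  expect_equal(up$r_s, 1)
  down <- correlate_abundance(c(13, 8, 5, 3, 2, 1), c(2, 4, 8, 16, 32, 64))
  expect_equal(down$r_s, -1)

  # ties handled by average ranks: compare with explicit Pearson on ranks
  x <- c(1, 2, 2, 4, 7); y <- c(10, 20, 30, 40, 35)
  got <- correlate_abundance(x, y)
  expect_equal(got$r_s, cor(rank(x), rank(y)))

  expect_error(correlate_abundance(c(1, 1, 1, 1, 1), 1:5), "constant")
  expect_error(correlate_abundance(1:4, 4:1), "at least 5")
})

test_that("planted monotone abundance-expression relation is detected", {
  set.seed(50)
  n <- 30
  abundance <- sort(rlnorm(n, 0, 1))
  weights <- abundance * rlnorm(n, 0, 0.4)   # noisy monotone link
  lib <- 2e5
  counts <- as.integer(rmultinom(1, lib, c(weights, sum(weights)))[, 1])[1:n]
  cpm <- counts / lib * 1e6
  res <- correlate_abundance(cpm, abundance)
  expect_gt(res$r_s, 0)
  expect_lt(res$p_value, 0.05)
})

test_that("expression_patterns recovers planted tissue patterns end-to-end", {
  set.seed(51)
  n_fam <- 8
  fams <- tibble::tibble(
    name = sprintf("F%02d", 1:n_fam),
    reference = vapply(1:n_fam, function(i)
      build_reference(make_consensus(100 + 7 * i, 0.6, 60 + i)), character(1)))
  planted <- rep(c("P1", "P2", "P3", "P4"), each = 2)
  weight_of <- function(p, tissue) {
    switch(p,
           P1 = c(ant = 1, ov = 1, te = 1),
           P2 = c(ant = 1, ov = 0.05, te = 0.05),
           P3 = c(ant = 0.1, ov = 1, te = 1),
           P4 = c(ant = 0.05, ov = 1, te = 0.02))[[tissue]]
  }
  samples <- c(ant1 = "ant", ant2 = "ant", ant3 = "ant", ov = "ov", te = "te")
  counts <- tibble::tibble(family = fams$name)
  for (s in names(samples)) {
    w <- vapply(planted, weight_of, numeric(1), tissue = samples[[s]])
    names(w) <- fams$name
    rna <- sim_rnaseq(fams, w, background_fraction = 0.3,
                      library_size = 20000, seed = match(s, names(samples)))
    cnt <- count_rna_reads(rna, dplyr::rename(fams, family = name))
    counts[[s]] <- cnt$count[match(counts$family, cnt$family)]
  }
  counts <- dplyr::bind_rows(counts, tibble::tibble(
    family = "background", ant1 = 0L, ant2 = 0L, ant3 = 0L, ov = 0L, te = 0L))
  pat <- expression_patterns(counts,
                             groups = list(antenna = c("ant1", "ant2", "ant3"),
                                           ovary = "ov", testis = "te"))
  got <- pat$pattern[match(fams$name, pat$family)]
  expect_gte(mean(got == planted), 7 / 8)
})
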
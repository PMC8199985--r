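# Kimura-2P distances, read masking, overlap resolution, abundance,
# landscapes and family-table statistics.

test_that("kimura2p evaluates the closed form and flags its domain", {
  expect_equal(kimura2p(0, 0), 0)
  # independent evaluation through the split-log form
  expect_equal(kimura2p(0.1, 0.05),
               -0.5 * log(1 - 0.2 - 0.05) - 0.25 * log(1 - 0.1),
               tolerance = 1e-12)
  # one transversion in 4 aligned columns (ACGT vs ACGA)
  expect_equal(kimura2p(0, 0.25),
               -0.5 * log(0.75) - 0.25 * log(0.5), tolerance = 1e-12)
  expect_true(is.na(kimura2p(0.5, 0.2)))   # 1 - 2P - Q < 0
  expect_true(is.na(kimura2p(0, 0.5)))     # 1 - 2Q = 0
  expect_error(kimura2p(-0.1, 0), ">= 0")
  expect_error(kimura2p(0.8, 0.3), "<= 1")
})

test_that("K dominates the p-distance and is monotone on the valid domain", {
  set.seed(7)
  P <- runif(300, 0, 0.4); Q <- runif(300, 0, 0.3)
  valid <- (1 - 2 * P - Q) > 1e-6 & (1 - 2 * Q) > 1e-6
  K <- kimura2p(P[valid], Q[valid])
  expect_true(all(K >= P[valid] + Q[valid] - 1e-12))
  # strict monotonicity in each argument
  expect_true(all(kimura2p(P[valid] + 1e-4, Q[valid]) > K))
  expect_true(all(kimura2p(P[valid], Q[valid] + 1e-4) > K))
})

test_that("map_reads finds planted hits with correct P/Q and strands", {
  ref <- build_reference(make_consensus(100, 0.6, 21))
  refs <- tibble::tibble(family = "fam", reference = ref)
  read <- substr(ref, 21, 170)  # exact 150-bp substring
  hits <- map_reads(tibble::tibble(id = "r1", seq = read), refs)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$P, 0)
  expect_equal(hits$Q, 0)
  expect_equal(hits$K, 0)
  expect_equal(hits$end - hits$start, 150)

  # reverse-complemented read: minus-strand hit, identical statistics
  hits_rc <- map_reads(tibble::tibble(id = "r1", seq = revcomp(read)), refs)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$P, hits$P)
  expect_equal(hits_rc$Q, hits$Q)
  expect_equal(hits_rc$matched_cols, hits$matched_cols)

  # random reads yield no hit at the default score floor
  set.seed(22)
  rand <- tibble::tibble(id = sprintf("n%d", 1:50),
                         seq = vapply(1:50, function(i)
                           satkit:::random_dna(150, 0.5), character(1)))
  expect_equal(nrow(map_reads(rand, refs)), 0)

  expect_error(map_reads(rand, refs[0, ]), "empty")
})

test_that("resolve_overlaps implements the documented greedy rule", {
  h <- tibble::tibble(read = "r", family = c("a", "b"),
                      start = c(0L, 0L), end = c(100L, 100L),
                      matched_cols = c(100L, 100L), P = 0, Q = 0, K = 0,
                      score = c(50, 40), strand = "+")
  kept <- resolve_overlaps(h)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$family, "a")

  h2 <- tibble::tibble(read = "r", family = c("a", "b"),
                       start = c(0L, 120L), end = c(100L, 150L),
                       matched_cols = 1L, P = 0, Q = 0, K = 0,
                       score = c(50, 40), strand = "+")
  expect_equal(nrow(resolve_overlaps(h2)), 2)

  # randomized hit sets against the independent greedy oracle
  set.seed(30)
  for (trial in 1:25) {
    n <- sample(2:5, 1)
    start <- sample(0:120, n)
    end <- pmin(150L, start + sample(20:80, n, replace = TRUE))
    score <- sample(30:90, n)
    h3 <- tibble::tibble(read = "r", family = letters[seq_len(n)],
                         start = as.integer(start), end = as.integer(end),
                         matched_cols = 1L, P = 0, Q = 0, K = 0,
                         score = score, strand = "+")
    kept3 <- resolve_overlaps(h3)
    oracle <- greedy_resolve_oracle(start, end, score)
    expect_equal(nrow(kept3), nrow(oracle))
    expect_equal(sum(kept3$end - kept3$start), sum(oracle$end - oracle$start))
  }
})

test_that("family abundance and weighted divergence follow their formulas", {
  hits <- tibble::tibble(read = c("r1", "r2"), family = "fam",
                         start = c(0L, 0L), end = c(100L, 20L),
                         matched_cols = c(100L, 300L), P = 0, Q = 0,
                         K = c(0.10, 0.20), score = 50, strand = "+")
  ab <- family_abundance(hits, total_bp = 150000)
  expect_equal(ab$proportion, 120 / 150000)

  dv <- family_divergence(hits)
  expect_equal(dv$divergence_pct, 17.5)  # (0.1*100 + 0.2*300) / 400 * 100

  expect_equal(nrow(family_abundance(hits[0, ], 1000)), 0)

  # undefined K contributes to abundance but not to divergence
  hits$K[1] <- NA
  expect_equal(family_abundance(hits, 150000)$proportion, 120 / 150000)
  expect_equal(family_divergence(hits)$divergence_pct, 20)
})

test_that("landscape bins masked bp by floor(100K) capped at 49", {
  hits <- tibble::tibble(read = c("a", "b", "c"), family = "f",
                         start = 0L, end = c(100L, 50L, 10L),
                         matched_cols = 100L, P = 0, Q = 0,
                         K = c(0.043, 0, 0.9), score = 50, strand = "+")
  ls <- landscape(hits, total_bp = 1000)
  expect_equal(ls$bp[ls$bin_low == 4], 100)
  expect_equal(ls$bp[ls$bin_low == 0], 50)
  expect_equal(ls$bp[ls$bin_low == 49], 10)
  expect_equal(ls$bin_high, ls$bin_low + 1)
  expect_equal(sum(ls$bp), sum(hits$end - hits$start))
})

test_that("summary statistics reproduce the published satellitome table", {
  fam <- load_family_table("fixture")
  st <- summarize_table(fam)
  expect_equal(st$length_bp[st$statistic == "Mean"], 235.23, tolerance = 1e-4)
  expect_equal(st$length_bp[st$statistic == "Median"], 165)
  expect_equal(st$length_bp[st$statistic == "SD"], 223.13, tolerance = 1e-4)
  expect_equal(round(st$proportion_pct[st$statistic == "Total"], 2), 8.05)

  # the printed SD is the sample SD: the population SD would be ~220.25
  n <- nrow(fam)
  pop_sd <- sd(fam$length_bp) * sqrt((n - 1) / n)
  expect_equal(round(pop_sd, 2), 220.25)
  expect_false(isTRUE(all.equal(pop_sd, 223.13, tolerance = 1e-3)))

  two <- fam[c(1, 1), ]
  st2 <- summarize_table(two)
  expect_equal(st2$length_bp[st2$statistic == "SD"], 0)
})

test_that("masked bp is conserved through overlap resolution", {
  sim <- tiny_satellitome()
  refs <- tibble::tibble(family = c("famA", "famB"),
                         reference = vapply(sim$specs$monomer, build_reference,
                                            character(1), USE.NAMES = FALSE))
  rd <- sample_reads(sim$reads, 600, seed = 31)
  hits <- map_reads(rd, refs)
  res <- resolve_overlaps(hits)
  total_bp <- sum(nchar(rd$seq))
  masked <- sum(res$end - res$start)
  expect_lte(masked, total_bp)
  # per-read masked bp never exceeds the read length
  per_read <- res |> dplyr::group_by(read) |>
    dplyr::summarise(bp = sum(end - start))
  expect_true(all(per_read$bp <= 150))
})
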
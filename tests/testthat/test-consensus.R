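# Monomer extraction, rotation alignment, consensus building, family
# grouping and naming.

test_that("extract_monomers cuts windows and drops the tail", {
  expect_equal(extract_monomers("ATCATCATC", 3), c("ATC", "ATC", "ATC"))
  rep500 <- strrep("A", 500)
  m <- extract_monomers(rep500, 165)
  expect_length(m, 3)
  expect_true(all(nchar(m) == 165))
  expect_error(extract_monomers("ATCATC", 5), "fewer than 2")
})

test_that("monomers cut from a simulated array stay close to the truth", {
  mono <- make_consensus(100, 0.65, 8)
  arr <- paste(vapply(1:10, function(i) mutate_copy(mono, 0.05), character(1)),
               collapse = "")
  ms <- extract_monomers(arr, 100)
  expect_length(ms, 10)
  mref <- strsplit(mono, "")[[1]]
  for (m in ms) {
    expect_lt(mean(strsplit(m, "")[[1]] != mref), 0.1)
  }
})

test_that("rotate_align recovers rotations and minimizes edit distance", {
  expect_equal(rotate_align("CGTA", "ACGT")[c("rotation", "distance")],
               list(rotation = 1L, distance = 0L))
  expect_equal(rotate_align("ACGT", "ACGT")[c("rotation", "distance")],
               list(rotation = 0L, distance = 0L))
  expect_equal(rotate_align("ACGT", "ACGA")$distance, 1L)

  # brute-force oracle over all rotations with an independent DP distance
  set.seed(3)
  for (trial in 1:10) {
    a <- satkit:::random_dna(12, 0.5)
    b <- satkit:::random_dna(12, 0.5)
    ra <- rotate_align(a, b)
    dists <- vapply(0:11, function(r) {
      dp_edit_distance(satkit:::rotate_seq(a, r), b)
    }, numeric(1))
    expect_equal(ra$distance, min(dists))
    expect_equal(ra$rotation, which.min(dists) - 1L)
  }
})

test_that("build_consensus takes column majorities with documented ties", {
  expect_equal(build_consensus(c("ACGT", "ACGT", "ACGA")), "ACGT")
  # final column split 2/2 between C and A resolves alphabetically to A
  expect_equal(build_consensus(c("GGGC", "GGGC", "GGGA", "GGGA"),
                               rotate = FALSE), "GGGA")
  expect_error(build_consensus("ACGT"), "at least 2")
})

test_that("consensus of many diverged monomers recovers the ancestor", {
  mono <- make_consensus(80, 0.6, 9)
  set.seed(10)
  ms <- vapply(1:50, function(i) mutate_copy(mono, 0.10), character(1))
  cons <- build_consensus(ms)
  expect_lte(satkit:::rotation_distance(cons, mono), 2)
})

test_that("build_consensus is invariant under circular rotation of input", {
  mono <- make_consensus(60, 0.6, 12)
  set.seed(13)
  ms <- vapply(1:20, function(i) mutate_copy(mono, 0.05), character(1))
  c1 <- build_consensus(ms)
  rot <- vapply(ms, satkit:::rotate_seq, character(1), r = 17, USE.NAMES = FALSE)
  c2 <- build_consensus(rot)
  expect_equal(satkit:::rotation_distance(c1, c2), 0)
})

test_that("assign_subfamilies groups by similarity and is order-invariant", {
  a <- make_consensus(120, 0.65, 14)
  expect_equal(assign_subfamilies(c(a, a))$family_group, c(1L, 1L))

  b <- make_consensus(120, 0.65, 15)  # unrelated: far below 80% identity
  expect_equal(dplyr::n_distinct(assign_subfamilies(c(a, b))$family_group), 2L)

  subs <- c(a, mutate_copy(a, 0.12, seed = 1), mutate_copy(a, 0.12, seed = 2))
  g1 <- assign_subfamilies(subs)
  expect_equal(dplyr::n_distinct(g1$family_group), 1L)

  g2 <- assign_subfamilies(rev(subs))
  expect_equal(dplyr::n_distinct(g2$family_group), 1L)
})

test_that("name_families encodes rank and monomer length", {
  fams <- tibble::tibble(consensus = c(strrep("A", 165), strrep("C", 293),
                                       strrep("G", 208)),
                         proportion = c(2.13, 0.067, 0.46))
  nm <- name_families(fams, prefix = "Rpro")
  expect_equal(nm$name, c("RproSat01-165", "RproSat02-208", "RproSat03-293"))
  nm2 <- name_families(fams[3, ], prefix = "Xabc")
  expect_equal(nm2$name, "XabcSat01-208")

  # ties in proportion break by decreasing length then consensus
  tied <- tibble::tibble(consensus = c(strrep("A", 50), strrep("A", 100)),
                         proportion = c(1, 1))
  expect_equal(name_families(tied)$name, c("RproSat01-100", "RproSat02-50"))
})

test_that("build_reference applies the max(2, ceiling(200/L)) copy rule", {
  expect_equal(nchar(build_reference(strrep("A", 165))), 330)
  expect_equal(nchar(build_reference(strrep("A", 31))), 217)   # 7 copies
  expect_equal(nchar(build_reference(strrep("A", 980))), 1960)
  tel <- declare_motif_family("telomeric", "TTAGG")
  expect_equal(nchar(tel$reference), 200)  # 40 copies of 5 bp
  expect_error(build_reference("ACG"), ">= 4")
})
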
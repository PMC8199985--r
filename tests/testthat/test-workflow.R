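# Configuration round-trips, the packaged family table, and the staged
# pipeline runner.

test_that("configuration round-trips losslessly through YAML", {
  cfg <- satkit_config(seed = 42, k = 15, species_prefix = "Xyzw",
                       min_cpm = 60)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(unclass(back), unclass(cfg))
  expect_equal(satkit:::config_hash(back), satkit:::config_hash(cfg))
})

test_that("the packaged family table matches the published satellitome", {
  fam <- load_family_table("fixture")
  expect_equal(nrow(fam), 39)
  expect_equal(fam$name[1], "RproSat01-165")
  expect_equal(fam$n_clusters[1], 38L)
  expect_equal(fam$proportion_pct[1], 2.13)
  expect_equal(fam$divergence_pct[fam$name == "RproSat13-293"], 28.28)
  expect_true(is.na(fam$n_clusters[fam$name == "RproSat13-293"]))

  # fixture integrity: frozen checksum of the shipped file
  path <- system.file("extdata", "rprolixus_satellitome_families.tsv",
                      package = "satkit")
  expect_equal(unname(tools::md5sum(path)), "4d42ee0d97bbee096efaa27ca48027d7")
})

test_that("malformed and empty family tables are rejected with positions", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tn_clusters\tproportion_pct\tlength_bp\tat_pct\tdivergence_pct",
               "Fam01\t1\t2.13\t165\t72.1\t13.42",
               "Fam02\t1\tnot_a_number\t169\t69.2\t9.81"), tmp)
  expect_error(load_family_table(tmp), "line 3")

  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_error(load_family_table(empty), "missing or empty")
})

test_that("run_pipeline writes a provenance-stamped, reproducible tree", {
  cfg <- satkit_config(
    seed = 7, cluster_sample = 700, quant_sample = 2000, species_prefix = "Test",
    families = list(name = "fam1", monomer = make_consensus(80, 0.65, 3),
                    target_proportion = 0.03, divergence = 0.04),
    genome_length = 2e5, coverage = 1.5,
    stages = c(simulate = TRUE, discover = TRUE, consensus = TRUE,
               quantify = TRUE, relations = FALSE))
  out1 <- withr::local_tempdir()
  res <- run_pipeline(cfg, out1)
  expect_s3_class(res, "satkit_satellitome")
  for (f in c("genome.fa", "truth.bed", "truth.tsv", "reads.fastq",
              "clusters.tsv", "family_table.tsv", "hits.tsv", "landscape.csv")) {
    expect_true(file.exists(file.path(out1, f)), label = f)
  }
  header <- readLines(file.path(out1, "family_table.tsv"), n = 3)
  expect_true(any(grepl("^# config:", header)))
  expect_true(any(grepl("^# seed: 7", header)))

  # reruns with the same config are byte-identical
  out2 <- withr::local_tempdir()
  run_pipeline(cfg, out2)
  for (f in c("genome.fa", "reads.fastq", "family_table.tsv")) {
    expect_identical(readLines(file.path(out1, f)), readLines(file.path(out2, f)),
                     label = f)
  }

  # recovered family table is close to the planted truth
  fam <- res$families
  expect_equal(nrow(fam), 1)
  expect_equal(fam$length_bp, 80)
  expect_lt(abs(fam$proportion_pct - 3) / 3, 0.25)
})

test_that("a stage consuming missing input names the absent artifact", {
  cfg <- satkit_config(seed = 1, stages = c(simulate = FALSE, discover = TRUE,
                                            consensus = TRUE, quantify = TRUE,
                                            relations = FALSE))
  out <- withr::local_tempdir()
  expect_error(run_pipeline(cfg, out), "reads.fastq")
})

test_that("tidiers expose per-element tables and one-row summaries", {
  spec <- sat_family_spec("f", make_consensus(60, 0.6, 1), 0.02, 0.03)
  g <- build_genome(spec, 1e5, seed = 5)
  expect_equal(tidy(g), g$arrays)
  gl <- glance(g)
  expect_equal(gl$n_arrays, nrow(g$arrays))
  expect_equal(gl$satellite_fraction, g$families$proportion)

  D <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  msn <- build_msn(D)
  expect_equal(tidy(msn)$steps, 2)
  expect_true(glance(msn)$connected)

  res <- correlate_abundance(c(1, 2, 3, 4, 6), c(2, 3, 5, 8, 9))
  td <- tidy(res)
  expect_named(td, c("estimate", "p.value", "n", "method"))
  expect_equal(td$estimate, 1)
})
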
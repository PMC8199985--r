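# Parameter-recovery study: an eight-family synthetic satellitome processed
# end to end, with estimates matched back to the generator's truth tables.
# This is the package's standing validation experiment; the acceptance
# script and the test suite both run it.

#' Specification of the standard recovery study
#'
#' Eight satellite families spanning the abundance range 0.05-3% of the
#' genome (geometric spacing, so that estimation noise cannot permute the
#' rank order) and per-copy divergences 2-20% on the Kimura scale.  Monomer
#' lengths lie between 50 and 165 bp: at the study's read geometry (PE150,
#' insert 300) periods up to ~225 bp are detectable from polished cluster
#' representatives.  Higher-divergence families get shorter monomers,
#' mirroring the inverse trend seen in real satellitomes where old, diverged
#' families tend to be short-monomer ones.
#'
#' @param seed Integer seed used to draw the ancestral monomers.
#' @return A [sat_family_spec()] tibble of 8 families.
#' @export
recovery_study_spec <- function(seed = 1) {
  lens <- c(165L, 120L, 80L, 60L, 100L, 150L, 50L, 60L)
  at <- c(0.70, 0.60, 0.65, 0.55, 0.62, 0.68, 0.72, 0.58)
  monomers <- vapply(seq_along(lens), function(i) {
    make_consensus(lens[i], at[i], seed = child_seed(seed, 100 + i))
  }, character(1))
  sat_family_spec(
    name = sprintf("planted%02d", 1:8),
    monomer = monomers,
    target_proportion = c(3, 1.67, 0.93, 0.52, 0.29, 0.16, 0.09, 0.05) / 100,
    divergence = c(0.05, 0.12, 0.20, 0.16, 0.08, 0.10, 0.04, 0.02),
    n_arrays = c(3L, 2L, 2L, 1L, 1L, 1L, 1L, 1L))
}

#' Run the standard parameter-recovery study
#'
#' Simulates a genome from [recovery_study_spec()], generates 1X PE150
#' reads, runs the full characterization pipeline, and matches every
#' discovered family back to its planted ancestor by rotation- and
#' strand-aware consensus distance.
#'
#' @param seed Root seed for the whole study.
#' @param genome_length Genome size in bp (default 5e6).
#' @param coverage Read coverage (default 1).
#' @param cluster_sample Reads used for graph clustering (default 12000,
#'   about 0.36X at the default genome size — the low-coverage sampling
#'   regime the clustering stage is designed for).
#' @return A list with `truth` (per-family realized truth), `result` (the
#'   `satkit_satellitome`), and `recovery`: one row per planted family with
#'   the matched estimate, relative abundance error and divergence error in
#'   percentage points.
#' @export
run_recovery_study <- function(seed = 1, genome_length = 5e6, coverage = 1,
                               cluster_sample = 12000) {
  spec <- recovery_study_spec(seed)
  sim <- build_genome(spec, genome_length, seed = child_seed(seed, 1))
  reads <- sim_reads(sim, coverage = coverage, error_rate = 0.001,
                     seed = child_seed(seed, 2))
  cfg <- satkit_config(seed = child_seed(seed, 3),
                       cluster_sample = cluster_sample,
                       quant_sample = nrow(reads))
  result <- characterize_satellitome(reads, cfg)

  truth <- sim$families
  est <- result$families
  # match each planted monomer to the closest discovered consensus
  # (strand- and rotation-aware, normalized by monomer length)
  match_tbl <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    mono <- truth$monomer[i]
    d <- vapply(est$consensus, function(cons) {
      dd <- min(rotation_distance(cons, mono),
                rotation_distance(revcomp(cons), mono))
      dd / max(nchar(cons), nchar(mono))
    }, numeric(1))
    j <- which.min(d)
    tibble(family = truth$family[i], matched = est$name[j],
           consensus_dist = d[j])
  })
  recovery <- truth |>
    left_join(match_tbl, by = "family") |>
    left_join(select(est, name = "name", est_proportion_pct = "proportion_pct",
                     est_divergence_pct = "divergence_pct",
                     est_length = "length_bp"),
              by = c(matched = "name")) |>
    mutate(
      recovered = .data$consensus_dist <= 0.25,
      true_proportion_pct = 100 * .data$proportion,
      true_divergence_pct = 100 * .data$divergence,
      rel_abundance_error = (.data$est_proportion_pct -
                               .data$true_proportion_pct) /
        .data$true_proportion_pct,
      divergence_error_pp = .data$est_divergence_pct -
        .data$true_divergence_pct) |>
    select("family", "matched", "recovered", "consensus_dist",
           "true_proportion_pct", "est_proportion_pct", "rel_abundance_error",
           "true_divergence_pct", "est_divergence_pct", "divergence_error_pp",
           monomer_length = "est_length")
  list(truth = truth, result = result, recovery = recovery)
}
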
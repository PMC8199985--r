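# Pipeline orchestration: configuration, the end-to-end characterization
# wrapper (discover -> consensus -> quantify), the published-table loader,
# and the staged, file-writing pipeline runner with provenance headers.

#' Pipeline configuration
#'
#' Collects every tunable of the satellitome pipeline with its documented
#' default.  The object round-trips losslessly through YAML
#' ([write_config()] / [read_config()]).
#'
#' @param seed Root seed for every stochastic stage.
#' @param species_prefix Species abbreviation for family names.
#' @param cluster_sample Reads sampled for graph clustering (default 600000,
#'   capped at the available reads).
#' @param quant_sample Reads sampled for quantification (default 1000000,
#'   capped at the available reads).
#' @param k,min_shared Clustering graph parameters.
#' @param cluster_method `"louvain"` (default) or `"components"`, see
#'   [cluster_reads()].
#' @param min_cluster_proportion Cluster floor (default 1e-5 = 0.001%).
#' @param min_period,tandem_threshold Tandem-call parameters.
#' @param family_min_identity,family_min_coverage Family-joining thresholds.
#' @param min_score Alignment score floor for quantification hits.
#' @param min_hit_identity,min_hit_coverage Assembly-scan 90/90 thresholds
#'   (percent).
#' @param min_cpm,min_cpm_samples Expression filter (CPM > 50 in >= 2).
#' @param dominance Pattern-dominance threshold.
#' @param stages Named logical vector toggling pipeline stages.
#' @param ... Further fields stored verbatim (e.g. `families`, `paths`).
#' @return A `satkit_config` list.
#' @export
satkit_config <- function(seed = 1, species_prefix = "Rpro",
                          cluster_sample = 600000, quant_sample = 1000000,
                          k = 13, min_shared = 3,
                          cluster_method = "louvain",
                          min_cluster_proportion = 1e-5,
                          min_period = 4, tandem_threshold = 0.7,
                          family_min_identity = 0.8, family_min_coverage = 0.5,
                          min_score = 30,
                          min_hit_identity = 90, min_hit_coverage = 90,
                          min_cpm = 50, min_cpm_samples = 2, dominance = 0.7,
                          stages = c(simulate = TRUE, discover = TRUE,
                                     consensus = TRUE, quantify = TRUE,
                                     relations = TRUE),
                          ...) {
  cfg <- c(list(seed = seed, species_prefix = species_prefix,
                cluster_sample = cluster_sample, quant_sample = quant_sample,
                k = k, min_shared = min_shared,
                cluster_method = cluster_method,
                min_cluster_proportion = min_cluster_proportion,
                min_period = min_period, tandem_threshold = tandem_threshold,
                family_min_identity = family_min_identity,
                family_min_coverage = family_min_coverage,
                min_score = min_score,
                min_hit_identity = min_hit_identity,
                min_hit_coverage = min_hit_coverage,
                min_cpm = min_cpm, min_cpm_samples = min_cpm_samples,
                dominance = dominance, stages = as.list(stages)),
           list(...))
  stopifnot(cfg$tandem_threshold > 0, cfg$tandem_threshold <= 1,
            cfg$min_cluster_proportion >= 0, cfg$dominance > 0.5)
  structure(cfg, class = "satkit_config")
}

#' @rdname satkit_config
#' @param config A `satkit_config`.
#' @param path YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname satkit_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # partial configs are completed with the documented defaults
  merged <- utils::modifyList(unclass(satkit_config()), raw)
  structure(merged, class = "satkit_config")
}

config_hash <- function(config) rlang::hash(unclass(config))

provenance <- function(config) {
  list(tool = paste0("satkit ", as.character(utils::packageVersion("satkit"))),
       config = config_hash(config), seed = config$seed)
}

#' Load a satellite family table
#'
#' Reads a six-column family table (name, cluster count, genome proportion
#' in percent, repeat length in bp, A+T percent, Kimura divergence percent).
#' `"fixture"` loads the packaged 39-row table of the published *Rhodnius
#' prolixus* satellitome.
#'
#' @param path A TSV path, or `"fixture"`.
#' @return A typed tibble with columns `name`, `n_clusters`,
#'   `proportion_pct`, `length_bp`, `at_pct`, `divergence_pct`.
#' @export
load_family_table <- function(path = "fixture") {
  if (identical(path, "fixture")) {
    path <- system.file("extdata", "rprolixus_satellitome_families.tsv",
                        package = "satkit", mustWork = TRUE)
  }
  if (!file.exists(path) || file.size(path) == 0) {
    abort(sprintf("Family table '%s' is missing or empty.", path))
  }
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("name", "n_clusters", "proportion_pct", "length_bp", "at_pct",
            "divergence_pct")
  if (!identical(names(raw), need)) {
    abort(paste("Family table must have columns:", paste(need, collapse = ", ")))
  }
  for (col in need[-1]) {
    bad <- which(!is.na(raw[[col]]) & is.na(suppressWarnings(as.numeric(raw[[col]]))))
    if (length(bad)) {
      abort(sprintf("Malformed value in column '%s' at line %d.", col, bad[1] + 1))
    }
    raw[[col]] <- as.numeric(raw[[col]])
  }
  raw$n_clusters <- as.integer(raw$n_clusters)
  as_tibble(raw)
}

#' Characterize a satellitome from reads
#'
#' The analytical core of the pipeline: sample reads, cluster them on the
#' k-mer graph, call tandem clusters, build rotation-normalized consensus
#' sequences, group clusters into families/subfamilies, quantify abundance
#' and Kimura-2P divergence by read masking against dimer references, and
#' name families by decreasing abundance.
#'
#' @param reads Read tibble (`id`, `seq`); all reads available, sampling is
#'   governed by the config.
#' @param config A [satkit_config()].
#' @param declared_motifs Optional tibble from [declare_motif_family()] rows
#'   for short motifs (telomeric, microsatellites) that graph discovery
#'   cannot see.
#' @return A `satkit_satellitome` list:
#'   \describe{
#'     \item{clusters}{discovery table ([discover_clusters()] output)}
#'     \item{subfamilies}{`cluster`, `consensus`, `family_group`, `subfamily`}
#'     \item{references}{reference collection used for masking}
#'     \item{hits}{resolved hit tibble}
#'     \item{families}{named family table (`name`, `n_clusters`,
#'       `proportion_pct`, `length_bp`, `at_pct`, `divergence_pct`,
#'       `consensus`)}
#'     \item{landscape}{divergence landscape tibble}
#'   }
#' @export
characterize_satellitome <- function(reads, config = satkit_config(),
                                     declared_motifs = NULL) {
  n_cluster <- min(config$cluster_sample, nrow(reads))
  cl_sample <- sample_reads(reads, n_cluster, seed = child_seed(config$seed, 1),
                            by_pair = TRUE)
  clusters <- discover_clusters(
    cl_sample, k = config$k, min_shared = config$min_shared,
    min_proportion = config$min_cluster_proportion,
    min_period = config$min_period, threshold = config$tandem_threshold,
    method = config$cluster_method %||% "louvain")

  tand <- filter(clusters, .data$tandem & !is.na(.data$period))
  cons_tbl <- purrr::map_dfr(seq_len(nrow(tand)), function(i) {
    rep_seq <- tand$representative[i]
    period <- tand$period[i]
    if (floor(nchar(rep_seq) / period) < 2) return(tibble())
    mono <- extract_monomers(rep_seq, period)
    cons <- if (length(mono) >= 2) build_consensus(mono) else mono[1]
    if (nchar(cons) < 4) return(tibble())
    tibble(cluster = tand$cluster[i], consensus = cons,
           cluster_bp = tand$bp[i])
  })
  if (nrow(cons_tbl) == 0) {
    abort("No tandem cluster yielded a consensus; nothing to quantify.")
  }

  grouped <- assign_subfamilies(cons_tbl,
                                min_identity = config$family_min_identity,
                                min_coverage = config$family_min_coverage) |>
    mutate(subfamily = paste0("G", .data$family_group, ".", .data$cluster))

  refs <- tibble(family = grouped$subfamily,
                 reference = vapply(grouped$consensus, build_reference,
                                    character(1), USE.NAMES = FALSE))
  family_of <- setNames(paste0("G", grouped$family_group), grouped$subfamily)
  if (!is.null(declared_motifs)) {
    refs <- bind_rows(refs, select(declared_motifs, family = "family",
                                   reference = "reference"))
    family_of <- c(family_of, setNames(declared_motifs$family,
                                       declared_motifs$family))
  }

  # consensus-polishing pass: map a read subsample to the draft references
  # and majority-correct each subfamily consensus with the reads it attracts
  # (small clusters yield too few monomers for an error-free consensus, and
  # a consensus error of e% inflates the divergence estimate by ~e pp)
  pol_reads <- sample_reads(reads, min(8000, nrow(reads)),
                            seed = child_seed(config$seed, 4))
  pre_hits <- map_reads(pol_reads, refs, min_score = config$min_score)
  seq_of <- setNames(pol_reads$seq, pol_reads$id)
  grouped$consensus <- vapply(seq_len(nrow(grouped)), function(i) {
    rids <- unique(pre_hits$read[pre_hits$family == grouped$subfamily[i]])
    if (length(rids) < 3) return(grouped$consensus[i])
    polish_consensus(grouped$consensus[i], unname(seq_of[rids]))
  }, character(1))
  refs_polished <- tibble(family = grouped$subfamily,
                          reference = vapply(grouped$consensus, build_reference,
                                             character(1), USE.NAMES = FALSE))
  if (!is.null(declared_motifs)) {
    refs_polished <- bind_rows(refs_polished,
                               select(declared_motifs, family = "family",
                                      reference = "reference"))
  }
  refs <- refs_polished

  n_quant <- min(config$quant_sample, nrow(reads))
  q_reads <- sample_reads(reads, n_quant, seed = child_seed(config$seed, 2))
  total_bp <- sum(nchar(q_reads$seq))
  hits <- map_reads(q_reads, refs, min_score = config$min_score) |>
    resolve_overlaps()

  ab <- family_abundance(hits, total_bp, family_of = family_of)
  dv <- family_divergence(hits, family_of = family_of)

  # family-level consensus: the group's largest cluster's consensus;
  # declared motifs carry their own.
  grp_cons <- grouped |>
    group_by(group = paste0("G", .data$family_group)) |>
    arrange(desc(.data$cluster_bp), .by_group = TRUE) |>
    summarise(consensus = dplyr::first(.data$consensus),
              n_clusters = dplyr::n(), .groups = "drop")
  if (!is.null(declared_motifs)) {
    grp_cons <- bind_rows(grp_cons,
                          tibble(group = declared_motifs$family,
                                 consensus = declared_motifs$consensus,
                                 n_clusters = NA_integer_))
  }

  fam <- grp_cons |>
    left_join(ab, by = c(group = "family")) |>
    left_join(select(dv, "family", "divergence_pct"), by = c(group = "family")) |>
    mutate(proportion = tidyr::replace_na(.data$proportion, 0)) |>
    name_families(prefix = config$species_prefix) |>
    mutate(proportion_pct = 100 * .data$proportion,
           length_bp = nchar(.data$consensus),
           at_pct = 100 * at_fraction(.data$consensus)) |>
    select("name", "n_clusters", "proportion_pct", "length_bp", "at_pct",
           "divergence_pct", "consensus", group = "group",
           masked_bp = "masked_bp")

  name_of_group <- setNames(fam$name, fam$group)
  lsc <- landscape(hits, total_bp,
                   family_of = setNames(name_of_group[unname(family_of)],
                                        names(family_of)))
  subfam <- grouped |>
    mutate(family = unname(name_of_group[paste0("G", .data$family_group)])) |>
    select("cluster", "subfamily", "family", "consensus")

  structure(list(clusters = clusters, subfamilies = subfam,
                 references = refs, hits = hits, families = fam,
                 landscape = lsc, total_bp = total_bp, config = config),
            class = "satkit_satellitome")
}

#' @export
print.satkit_satellitome <- function(x, ...) {
  cat(sprintf("<satkit_satellitome> %d famil(ies) from %d tandem cluster(s); total satellite fraction %.3f%%\n",
              nrow(x$families), sum(x$clusters$tandem, na.rm = TRUE),
              sum(x$families$proportion_pct)))
  print(select(x$families, -"consensus"), ...)
  invisible(x)
}

#' Run the staged satellitome pipeline
#'
#' Executes the toggled stages — simulate, discover/consensus/quantify
#' (one characterization pass), relations — writing every output table with
#' a provenance header (tool version, config hash, seed).  Reruns with the
#' same config are identical.
#'
#' @param config A [satkit_config()].  For the simulate stage, `config$families`
#'   holds a [sat_family_spec()]-shaped list and `config$genome_length` /
#'   `config$coverage` the genome size and read coverage.
#' @param outdir Output directory (created if needed).
#' @return The `satkit_satellitome` (invisibly `NULL` when the characterize
#'   stages are toggled off), with outputs on disk.
#' @export
run_pipeline <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  prov <- provenance(config)
  stages <- config$stages
  on_stage <- function(s) isTRUE(stages[[s]])
  reads_path <- file.path(outdir, "reads.fastq")

  if (on_stage("simulate")) {
    spec <- do.call(sat_family_spec, config$families)
    sim <- build_genome(spec, genome_length = config$genome_length,
                        seed = child_seed(config$seed, 10))
    write_fasta_tbl(sim$genome, file.path(outdir, "genome.fa"))
    write_truth(sim, bed_path = file.path(outdir, "truth.bed"),
                tsv_path = file.path(outdir, "truth.tsv"))
    reads <- sim_reads(sim, coverage = config$coverage %||% 1,
                       error_rate = config$error_rate %||% 0.001,
                       seed = child_seed(config$seed, 11))
    write_fastq_tbl(reads, reads_path)
  }

  result <- NULL
  if (on_stage("discover") || on_stage("quantify")) {
    if (!file.exists(reads_path)) {
      abort(sprintf("Missing pipeline artifact '%s': enable the simulate stage or provide reads.", reads_path))
    }
    reads <- read_fastq_tbl(reads_path)
    motifs <- NULL
    if (!is.null(config$motifs)) {
      motifs <- bind_rows(lapply(names(config$motifs), function(nm) {
        declare_motif_family(nm, config$motifs[[nm]])
      }))
    }
    result <- characterize_satellitome(reads, config, declared_motifs = motifs)
    write_tsv_provenance(
      select(result$clusters, "cluster", "n_reads", "bp", "proportion",
             "tandem", "period"),
      file.path(outdir, "clusters.tsv"), prov)
    reps <- filter(result$clusters, .data$tandem)
    if (nrow(reps)) {
      write_fasta_tbl(tibble(id = paste0(reps$cluster, " period=", reps$period),
                             seq = reps$representative),
                      file.path(outdir, "representatives.fa"))
    }
    write_fasta_tbl(tibble(id = result$subfamilies$subfamily,
                           seq = result$subfamilies$consensus),
                    file.path(outdir, "subfamily_consensus.fa"))
    write_fasta_tbl(tibble(id = result$families$name,
                           seq = result$families$consensus),
                    file.path(outdir, "family_consensus.fa"))
    write_tsv_provenance(select(result$families, -"consensus", -"group"),
                         file.path(outdir, "family_table.tsv"), prov)
    write_tsv_provenance(result$hits, file.path(outdir, "hits.tsv"), prov)
    write_tsv_provenance(result$landscape, file.path(outdir, "landscape.csv"),
                         prov, sep = ",")
  }

  if (on_stage("relations")) {
    cons_fa <- file.path(outdir, "subfamily_consensus.fa")
    if (is.null(result) && !file.exists(cons_fa)) {
      abort(sprintf("Missing pipeline artifact '%s': enable the consensus stage first.", cons_fa))
    }
    sf <- result$subfamilies
    if (nrow(sf) >= 2) {
      sim_hits <- pairwise_similarity(
        setNames(sf$consensus, sf$subfamily),
        seed = child_seed(config$seed, 20))
      write_tsv_provenance(sim_hits, file.path(outdir, "similarity.tsv"), prov)
    }
    multi <- sf |> count(.data$family) |> filter(.data$n >= 2)
    ab <- setNames(result$families$proportion_pct, result$families$name)
    for (famname in multi$family) {
      sub <- filter(sf, .data$family == famname)
      D <- pairwise_distance(setNames(sub$consensus, sub$subfamily))
      msn <- build_msn(D, lengths = setNames(nchar(sub$consensus), sub$subfamily))
      write_tsv_provenance(msn$edges,
                           file.path(outdir, paste0("msn_", famname, ".tsv")),
                           prov)
      write_msn_graphml(msn, file.path(outdir, paste0("msn_", famname, ".graphml")))
    }
  }
  invisible(result)
}
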
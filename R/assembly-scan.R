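# Assembly scan: locate family/subfamily monomers in an assembly, accept
# hits under the 90/90 rule (>= 90% single-HSP query coverage and >= 90%
# identity), count monomers per scaffold and compute subfamily co-occurrence.
# Alignment is delegated to NCBI blastn (makeblastdb + blastn on PATH), the
# tool of choice for all-HSP scans of monomer queries against scaffolds.

#' Scan an assembly for satellite monomers
#'
#' Runs blastn of every consensus (query) against the assembly scaffolds,
#' both strands, and keeps hits passing the 90/90 rule: single-HSP query
#' coverage >= `min_coverage` percent and identity >= `min_identity` percent.
#'
#' @param assembly Tibble with `id`/`seq` columns, or a FASTA path.
#' @param consensuses Tibble with `name`/`consensus` columns, or a named
#'   character vector (one entry per family or subfamily).
#' @param min_identity,min_coverage Acceptance thresholds in percent
#'   (defaults 90/90).
#' @param task blastn task (default "blastn-short" below 50 bp queries,
#'   "blastn" otherwise, chosen per query automatically when `NULL`).
#' @return Hit tibble: `family`, `scaffold`, `start`, `end` (0-based
#'   half-open on the scaffold), `identity_pct`, `coverage_pct`, `strand`,
#'   `bitscore`.
#' @export
scan_assembly <- function(assembly, consensuses, min_identity = 90,
                          min_coverage = 90, task = NULL) {
  asm <- as_genome_tbl(assembly)
  if (nrow(asm) == 0 || sum(nchar(asm$seq)) == 0) abort("Assembly is empty.")
  cons <- as_consensus_tbl(consensuses)
  if (Sys.which("blastn") == "" || Sys.which("makeblastdb") == "") {
    abort("blastn/makeblastdb not found on PATH; the assembly scan requires the BLAST+ suite.")
  }
  td <- tempfile("satkit_blast_")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  db_fa <- file.path(td, "assembly.fa")
  q_fa <- file.path(td, "queries.fa")
  write_fasta_tbl(asm, db_fa)
  write_fasta_tbl(tibble(id = cons$name, seq = cons$consensus), q_fa)
  system2("makeblastdb", c("-in", db_fa, "-dbtype", "nucl"),
          stdout = FALSE, stderr = FALSE)
  out <- file.path(td, "hits.tsv")
  if (is.null(task)) {
    task <- if (min(nchar(cons$consensus)) < 50) "blastn-short" else "blastn"
  }
  status <- system2("blastn", c(
    "-query", q_fa, "-db", db_fa, "-task", task,
    "-evalue", "1e-3", "-dust", "no", "-max_target_seqs", "100000",
    "-outfmt", shQuote("6 qseqid sseqid pident length qcovhsp sstart send bitscore sstrand"),
    "-out", out), stdout = FALSE, stderr = FALSE)
  if (status != 0) abort("blastn failed.")
  if (file.size(out) == 0) {
    return(tibble(family = character(), scaffold = character(),
                  start = integer(), end = integer(), identity_pct = double(),
                  coverage_pct = double(), strand = character(),
                  bitscore = double()))
  }
  raw <- utils::read.table(out, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("family", "scaffold", "identity_pct",
                                         "length", "coverage_pct", "sstart",
                                         "send", "bitscore", "sstrand"))
  as_tibble(raw) |>
    filter(.data$identity_pct >= min_identity,
           .data$coverage_pct >= min_coverage) |>
    mutate(start = pmin(.data$sstart, .data$send) - 1L,
           end = pmax(.data$sstart, .data$send),
           strand = ifelse(.data$sstrand == "plus", "+", "-")) |>
    select("family", "scaffold", "start", "end", "identity_pct",
           "coverage_pct", "strand", "bitscore")
}

#' Apply the 90/90 acceptance rule to a raw hit table
#'
#' Exposed separately so the rule can be tested and re-applied with other
#' thresholds.
#'
#' @param hits Tibble with `identity_pct` and `coverage_pct` columns.
#' @param min_identity,min_coverage Thresholds in percent.
#' @return The subset of accepted hits.
#' @export
filter_hits_9090 <- function(hits, min_identity = 90, min_coverage = 90) {
  filter(hits, .data$identity_pct >= min_identity,
         .data$coverage_pct >= min_coverage)
}

#' Per-scaffold subfamily hit counts
#'
#' @param hits Accepted hit tibble from [scan_assembly()].
#' @param monomer_lengths Optional named vector of monomer lengths; when
#'   given, a monomer-equivalent count (masked bp / monomer length, rounded
#'   down) is added.
#' @return Tibble `scaffold`, `family`, `n_hits`, `masked_bp`,
#'   `monomer_equivalents` (if lengths given).
#' @export
scaffold_hit_counts <- function(hits, monomer_lengths = NULL) {
  out <- hits |>
    group_by(.data$scaffold, .data$family) |>
    summarise(n_hits = dplyr::n(),
              masked_bp = sum(.data$end - .data$start), .groups = "drop")
  if (!is.null(monomer_lengths)) {
    out <- mutate(out, monomer_equivalents =
                    floor(.data$masked_bp / unname(monomer_lengths[.data$family])))
  }
  out
}

#' Subfamily co-occurrence across scaffolds
#'
#' With `S_i` the set of scaffolds holding at least one accepted hit of
#' subfamily *i*, the shared fraction of a pair is the Jaccard index
#' `|S_i ∩ S_j| / |S_i ∪ S_j|` (symmetric).  An asymmetric variant
#' `|S_i ∩ S_j| / |S_i|` is available with `method = "conditional"`.
#'
#' @param hits Accepted hit tibble from [scan_assembly()].
#' @param families Optional vector fixing the row/column order (defaults to
#'   families present in `hits`).
#' @param method `"jaccard"` (default) or `"conditional"`.
#' @return A square matrix of shared fractions in `[0, 1]`; `NA` where both
#'   scaffold sets are empty.  Class `satkit_cooccurrence`.
#' @export
cooccurrence <- function(hits, families = NULL, method = c("jaccard", "conditional")) {
  method <- match.arg(method)
  families <- families %||% sort(unique(hits$family))
  sets <- lapply(families, function(f) unique(hits$scaffold[hits$family == f]))
  names(sets) <- families
  n <- length(families)
  M <- matrix(NA_real_, n, n, dimnames = list(families, families))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- sets[[i]]; b <- sets[[j]]
      if (length(a) == 0 && length(b) == 0) next
      inter <- length(intersect(a, b))
      M[i, j] <- switch(method,
        jaccard = inter / length(union(a, b)),
        conditional = if (length(a)) inter / length(a) else NA_real_)
    }
  }
  class(M) <- c("satkit_cooccurrence", class(M))
  M
}
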
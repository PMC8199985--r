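# Read simulators: genomic paired-end reads, assembly pseudo-reads and
# RNA-seq libraries with planted per-family expression.

## Shared paired-end engine.  `mode` controls insert placement: "stratified"
## spreads inserts evenly over the usable coordinate space with per-insert
## jitter (low-variance coverage), "uniform" samples i.i.d. uniform positions.
sim_pe_engine <- function(ids, seqs, n_pairs, read_len, insert_mean, error_rate,
                          mode, prefix = "read") {
  lens <- nchar(seqs)
  usable <- lens - insert_mean + 1
  if (all(usable < 1)) abort("All scaffolds are shorter than the insert length.")
  keep <- usable >= 1
  usable <- usable[keep]; seqs <- seqs[keep]; lens <- lens[keep]
  U <- sum(usable)
  if (mode == "stratified") {
    g <- floor(U * (seq_len(n_pairs) - runif(n_pairs)) / n_pairs)
    g <- sample(g)  # shuffle so read order carries no positional information
  } else {
    g <- floor(runif(n_pairs) * U)
  }
  cum <- cumsum(usable)
  scaf <- findInterval(g, cum, left.open = TRUE) + 1L
  offset <- g - c(0, head(cum, -1))[scaf]          # 0-based start within scaffold
  s1 <- offset + 1
  r1 <- substring(seqs[scaf], s1, s1 + read_len - 1)
  s2 <- offset + insert_mean - read_len + 1
  r2 <- revcomp(substring(seqs[scaf], s2, s2 + read_len - 1))
  flip <- runif(n_pairs) < 0.5                      # insert orientation
  tmp <- r1[flip]; r1[flip] <- r2[flip]; r2[flip] <- tmp
  if (error_rate > 0) {
    r1 <- add_seq_errors(r1, error_rate)
    r2 <- add_seq_errors(r2, error_rate)
  }
  pid <- sprintf("%s%07d", prefix, seq_len(n_pairs))
  tibble(
    id = c(paste0(pid, "/1"), paste0(pid, "/2")),
    pair = rep(pid, 2), mate = rep(c(1L, 2L), each = n_pairs),
    seq = c(r1, r2)
  ) |> arrange(.data$pair, .data$mate)
}

add_seq_errors <- function(seqs, error_rate) {
  out <- mutate_seqs(seqs, divergence = min(error_rate, 0.3), ts_tv_ratio = 0.5)
  as.character(out)
}

#' Simulate paired-end genomic reads
#'
#' Samples PE reads from a genome at a given fold coverage.  The number of
#' pairs is `ceiling(coverage * genome_length / (2 * read_len))`.  Base
#' qualities are constant ("I") when written to FASTQ.  The default
#' `"stratified"` placement spreads inserts near-evenly along the genome
#' (jittered systematic sampling), which keeps local coverage close to its
#' expectation; `"uniform"` gives classical i.i.d. (Poisson-like) sampling.
#'
#' @param genome A `satkit_genome`, a tibble with `id`/`seq` columns, or a
#'   path to a FASTA file.
#' @param coverage Fold coverage (> 0).
#' @param read_len Read length in bp (default 150).
#' @param insert_mean Insert size in bp (default 300; must be >= `read_len`).
#' @param error_rate Per-base substitution error rate (default 0).
#' @param seed Integer seed.
#' @param mode Insert placement: `"stratified"` (default) or `"uniform"`.
#' @return A tibble with columns `id`, `pair`, `mate`, `seq` (two rows per
#'   pair, mates in order).
#' @export
sim_reads <- function(genome, coverage, read_len = 150, insert_mean = 300,
                      error_rate = 0, seed = 1, mode = c("stratified", "uniform")) {
  mode <- match.arg(mode)
  g <- as_genome_tbl(genome)
  if (coverage <= 0) abort("`coverage` must be > 0.")
  if (read_len > insert_mean) abort("`read_len` must be <= `insert_mean`.")
  total <- sum(nchar(g$seq))
  if (all(nchar(g$seq) < insert_mean)) {
    abort("Genome is shorter than the insert length.")
  }
  n_pairs <- ceiling(coverage * total / (2 * read_len))
  with_seed(seed, sim_pe_engine(g$id, g$seq, n_pairs, read_len, insert_mean,
                                error_rate, mode))
}

#' Simulate assembly pseudo-reads
#'
#' Generates an error-free PE150 pseudo-read run from an assembly so that
#' assembly sequence can enter read-based stages.  Pairs are placed i.i.d.
#' uniformly over the usable coordinate space, so per-scaffold pair counts are
#' multinomial proportional to scaffold length.  Scaffolds shorter than the
#' insert are skipped with a warning.
#'
#' @param assembly Tibble with `id`/`seq` columns, or a FASTA path.
#' @param coverage Fold coverage.
#' @param seed Integer seed.
#' @param read_len,insert_mean Read geometry (defaults PE150, insert 300).
#' @return A read tibble as in [sim_reads()].
#' @export
assembly_pseudo_reads <- function(assembly, coverage, seed = 1,
                                  read_len = 150, insert_mean = 300) {
  g <- as_genome_tbl(assembly)
  if (nrow(g) == 0 || sum(nchar(g$seq)) == 0) abort("Assembly is empty.")
  short <- nchar(g$seq) < insert_mean
  if (any(short)) {
    warn(sprintf("Skipping %d scaffold(s) shorter than the insert (%d bp): %s",
                 sum(short), insert_mean,
                 paste(head(g$id[short], 5), collapse = ", ")))
    g <- g[!short, , drop = FALSE]
    if (nrow(g) == 0) abort("No scaffold is longer than the insert length.")
  }
  n_pairs <- ceiling(coverage * sum(nchar(g$seq)) / (2 * read_len))
  with_seed(seed, sim_pe_engine(g$id, g$seq, n_pairs, read_len, insert_mean,
                                error_rate = 0, mode = "uniform", prefix = "pseudo"))
}

as_genome_tbl <- function(x) {
  if (inherits(x, "satkit_genome")) return(x$genome)
  if (is.character(x) && length(x) == 1 && file.exists(x)) return(read_fasta_tbl(x))
  if (is.data.frame(x) && all(c("id", "seq") %in% names(x))) return(as_tibble(x))
  abort("Expected a satkit_genome, an id/seq tibble, or a FASTA path.")
}

#' Simulate a satellite RNA-seq library
#'
#' Draws reads multinomially: a read is background (random sequence emulating
#' the non-satellite transcriptome) with probability `background_fraction`,
#' otherwise it comes from one family's reference in proportion to that
#' family's expression weight.  Expected count for family *f* is
#' `weight_f / sum(weights) * (1 - background_fraction) * library_size`.
#'
#' @param families Tibble with columns `name` and `reference` (DNA string the
#'   reads are drawn from, typically [build_reference()] output).
#' @param expression Named numeric vector of non-negative expression weights,
#'   one per family (names matching `families$name`).
#' @param background_fraction Fraction of reads from background, in `[0, 1)`.
#' @param library_size Number of reads to draw.
#' @param seed Integer seed.
#' @param read_len Read length (default 150).
#' @param error_rate Per-base error rate for family reads (default 0.005).
#' @return A tibble `id`, `seq`, `origin` (`origin` is the truth label:
#'   family name or "background").
#' @export
sim_rnaseq <- function(families, expression, background_fraction = 0.5,
                       library_size = 1e5, seed = 1, read_len = 150,
                       error_rate = 0.005) {
  if (background_fraction < 0 || background_fraction >= 1) {
    abort("`background_fraction` must be in [0, 1).")
  }
  w <- expression[families$name]
  if (any(is.na(w))) abort("`expression` must be named for every family.")
  if (any(w < 0)) abort("Expression weights must be >= 0.")
  if (sum(w) == 0 && background_fraction == 0) {
    abort("All weights are zero and `background_fraction` is 0: nothing to draw.")
  }
  probs <- c(background_fraction,
             if (sum(w) > 0) (1 - background_fraction) * w / sum(w)
             else rep(0, length(w)))
  with_seed(seed, {
    counts <- as.integer(rmultinom(1, library_size, probs))
    out <- vector("list", length(counts))
    if (counts[1] > 0) {
      big <- random_dna(counts[1] * read_len, 0.5)
      s <- (seq_len(counts[1]) - 1) * read_len + 1
      out[[1]] <- tibble(seq = substring(big, s, s + read_len - 1),
                         origin = "background")
    }
    for (fi in seq_len(nrow(families))) {
      nf <- counts[fi + 1]
      if (nf == 0) next
      ref <- families$reference[fi]
      L <- nchar(ref)
      if (L < read_len) ref <- strrep(ref, ceiling(read_len / L) + 1)
      L <- nchar(ref)
      s <- sample.int(L - read_len + 1, nf, replace = TRUE)
      reads <- substring(ref, s, s + read_len - 1)
      rc <- runif(nf) < 0.5
      reads[rc] <- revcomp(reads[rc])
      if (error_rate > 0) reads <- add_seq_errors(reads, error_rate)
      out[[fi + 1]] <- tibble(seq = reads, origin = families$name[fi])
    }
    res <- bind_rows(out)
    res <- res[sample.int(nrow(res)), , drop = FALSE]
    mutate(res, id = sprintf("rna%07d", row_number()), .before = 1)
  })
}
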
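# Monomer extraction, rotation-aware alignment, consensus building, family
# assembly from cluster consensuses, and family naming.  Tandem monomers are
# circular: copies cut from an array are circular permutations of each other,
# so every comparison here is rotation-normalized first.

#' Cut a tandem representative into monomers
#'
#' Consecutive non-overlapping windows of length `period`; a trailing
#' fragment shorter than `period` is discarded.
#'
#' @param representative DNA string.
#' @param period Monomer length in bp (>= 4; representative must hold at
#'   least two monomers).
#' @return Character vector of `floor(L / period)` monomers.
#' @export
#' @examples
#' extract_monomers("ATCATCATC", 3)
extract_monomers <- function(representative, period) {
  if (period < 2) abort("`period` must be >= 2.")
  L <- nchar(representative)
  n <- floor(L / period)
  if (n < 2) abort("Representative holds fewer than 2 monomers at this period.")
  s <- (seq_len(n) - 1) * period + 1
  substring(representative, s, s + period - 1)
}

#' Find the best circular rotation of a monomer against a reference
#'
#' Considers every rotation of `monomer` and returns the one minimizing the
#' Levenshtein edit distance to `reference` (ties broken by the smallest
#' rotation offset).
#'
#' @param monomer,reference DNA strings (non-empty).
#' @return A list with `rotation` (0-based left-rotation offset), `distance`
#'   (minimized edit distance) and `rotated` (the rotated monomer).
#' @export
#' @examples
#' rotate_align("CGTA", "ACGT")  # rotation 1, distance 0
rotate_align <- function(monomer, reference) {
  if (nchar(monomer) == 0 || nchar(reference) == 0) {
    abort("Both sequences must be non-empty.")
  }
  n <- nchar(monomer)
  rots <- vapply(0:(n - 1), function(r) rotate_seq(monomer, r), character(1))
  d <- as.integer(adist(rots, reference))
  best <- which.min(d)  # which.min returns the first (smallest r) minimum
  list(rotation = best - 1L, distance = d[best], rotated = rots[best])
}

## Rotation-minimized edit distance between two sequences (helper shared with
## the relations module).
rotation_distance <- function(a, b) {
  rotate_align(a, b)$distance
}

#' Build a majority-rule consensus from monomers
#'
#' Monomers are rotation-normalized to the longest monomer, aligned to it,
#' and a consensus is taken column by column over `{A, C, G, T, -}`:
#' gap-majority columns are removed and ties between bases are broken
#' alphabetically (A < C < G < T).  Single-base insertions relative to the
#' anchor are kept when present in a strict majority of monomers.
#'
#' @param monomers Character vector of at least 2 DNA strings.
#' @param rotate Set to `FALSE` when monomers are already in a common phase.
#' @return The consensus DNA string.
#' @export
#' @examples
#' build_consensus(c("ACGT", "ACGT", "ACGA"))
build_consensus <- function(monomers, rotate = TRUE) {
  if (length(monomers) < 2) abort("Need at least 2 monomers for a consensus.")
  anchor <- monomers[[which.max(nchar(monomers))]]
  others <- monomers
  if (rotate) {
    others <- vapply(monomers, function(m) rotate_align(m, anchor)$rotated,
                     character(1), USE.NAMES = FALSE)
  }
  L <- nchar(anchor)
  alphabet <- c(DNA_BASES, "-")
  if (all(nchar(others) == L)) {
    # ungapped fast path: pure column-majority over equal-length monomers
    m <- matrix(match(strsplit(paste(others, collapse = ""), "")[[1]], alphabet),
                nrow = L)
    counts <- apply(m, 1, tabulate, nbins = 5)  # 5 x L
    return(consensus_from_counts(counts, alphabet))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(others), Biostrings::DNAString(anchor),
    type = "global", substitutionMatrix = mat, gapOpening = 4, gapExtension = 1)
  ap <- as.character(Biostrings::alignedPattern(aln))
  as_ <- as.character(Biostrings::alignedSubject(aln))
  counts <- matrix(0L, nrow = 5, ncol = L, dimnames = list(alphabet, NULL))
  ins_tab <- list()
  for (i in seq_along(ap)) {
    pa <- strsplit(ap[i], "")[[1]]
    sa <- strsplit(as_[i], "")[[1]]
    anchor_col <- cumsum(sa != "-")
    keep <- sa != "-"
    idx <- match(pa[keep], alphabet)
    pos <- anchor_col[keep]
    ok <- !is.na(idx)
    counts <- counts + matrix(tabulate(idx[ok] + 5L * (pos[ok] - 1L),
                                       nbins = 5L * L), nrow = 5)
    ins <- which(!keep & pa != "-")
    for (j in ins) {
      key <- as.character(anchor_col[j])   # insertion after this anchor column
      ins_tab[[key]] <- c(ins_tab[[key]], pa[j])
    }
  }
  cons <- consensus_from_counts(counts, alphabet, collapse = FALSE)
  n <- length(ap)
  out <- character(0)
  for (p in 0:L) {
    key <- as.character(p)
    if (!is.null(ins_tab[[key]]) && length(ins_tab[[key]]) > n / 2) {
      tab <- sort(table(ins_tab[[key]]), decreasing = TRUE)
      out <- c(out, names(tab)[1])
    }
    if (p < L && !is.na(cons[p + 1])) out <- c(out, cons[p + 1])
  }
  paste(out, collapse = "")
}

## counts: 5 x L matrix over c(A,C,G,T,-).  Gap strictly-majority columns are
## dropped; among tied max bases the alphabetically first wins.
consensus_from_counts <- function(counts, alphabet, collapse = TRUE) {
  base_max <- apply(counts[1:4, , drop = FALSE], 2, max)
  drop <- counts[5, ] > base_max
  pick <- apply(counts[1:4, , drop = FALSE], 2, which.max)  # first max: A<C<G<T
  res <- ifelse(drop, NA_character_, DNA_BASES[pick])
  if (collapse) paste(res[!is.na(res)], collapse = "") else res
}

#' Refine a family consensus against its member reads
#'
#' Re-cuts every member read into period-length windows, rotation-normalizes
#' each window to the current consensus and rebuilds the majority consensus
#' from the full monomer set.  With tens of member reads this drives per-site
#' consensus error close to zero even for highly diverged families.
#'
#' @param consensus Initial consensus (e.g. from the cluster representative).
#' @param member_seqs Character vector of member read sequences.
#' @param max_monomers Cap on monomers used (default 200).
#' @return The refined consensus DNA string.
#' @export
refine_consensus <- function(consensus, member_seqs, max_monomers = 200) {
  period <- nchar(consensus)
  usable <- member_seqs[nchar(member_seqs) >= period]
  if (!length(usable)) return(consensus)
  mono <- unlist(lapply(usable, function(s) {
    n <- floor(nchar(s) / period)
    if (n < 1) return(character(0))
    st <- (seq_len(n) - 1) * period + 1
    substring(s, st, st + period - 1)
  }))
  if (length(mono) > max_monomers) {
    mono <- mono[round(seq(1, length(mono), length.out = max_monomers))]
  }
  # orient each monomer (strand), phase it to the current consensus, and
  # drop windows too far from it (reads of unrelated sequence that ended up
  # in the same cluster would otherwise poison the majority)
  aligned <- lapply(mono, function(m) {
    fw <- rotate_align(m, consensus)
    rv <- rotate_align(revcomp(m), consensus)
    if (rv$distance < fw$distance) rv else fw
  })
  dist_frac <- vapply(aligned, function(a) a$distance / period, numeric(1))
  oriented <- vapply(aligned[dist_frac <= 0.35], function(a) a$rotated,
                     character(1))
  if (length(oriented) < 2) return(consensus)
  build_consensus(c(consensus, oriented), rotate = FALSE)
}

#' Polish a consensus by majority vote of aligned reads
#'
#' Aligns reads to a tandem reference built from the consensus and replaces
#' each consensus position by the majority base over all aligned reads.
#' Because the reference is tandem, read phase is irrelevant: reference
#' columns fold back onto consensus positions modulo the monomer length.
#' Substitution-only: the consensus length is preserved (indel polishing is
#' left to the monomer-based [refine_consensus()]).
#'
#' @param consensus DNA string.
#' @param read_seqs Character vector of read sequences covering the family.
#' @param max_reads Cap on reads used (default 300).
#' @return The polished consensus DNA string.
#' @export
polish_consensus <- function(consensus, read_seqs, max_reads = 300) {
  L <- nchar(consensus)
  if (!length(read_seqs) || L < 4) return(consensus)
  if (length(read_seqs) > max_reads) {
    read_seqs <- read_seqs[round(seq(1, length(read_seqs),
                                     length.out = max_reads))]
  }
  copies <- ceiling(max(nchar(read_seqs)) / L) + 2
  ref <- strrep(consensus, copies)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  pats <- Biostrings::DNAStringSet(read_seqs)
  subj <- Biostrings::DNAString(ref)
  fw <- Biostrings::pairwiseAlignment(pats, subj, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 5, gapExtension = 2,
                                      scoreOnly = TRUE)
  rc <- Biostrings::DNAStringSet(revcomp(read_seqs))
  rv <- Biostrings::pairwiseAlignment(rc, subj, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 5, gapExtension = 2,
                                      scoreOnly = TRUE)
  oriented <- ifelse(rv > fw, as.character(rc), read_seqs)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(oriented),
                                       subj, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 5, gapExtension = 2)
  sr <- Biostrings::subject(aln)@range
  # per-reference-column coverage (approximate across small indels)
  cov <- tabulate(unlist(lapply(seq_along(sr), function(i) {
    sr@start[i]:(sr@start[i] + sr@width[i] - 1)
  })), nbins = nchar(ref))
  mm <- Biostrings::mismatchTable(aln)
  base_idx <- match(as.character(mm$PatternSubstring), DNA_BASES)
  pos <- mm$SubjectStart
  keep <- !is.na(base_idx) & pos >= 1 & pos <= nchar(ref)
  # fold reference columns onto consensus positions
  cpos <- (pos[keep] - 1) %% L + 1
  ccov <- numeric(L)
  for (cp in seq_len(copies)) {
    idx <- ((cp - 1) * L + 1):(cp * L)
    ccov <- ccov + cov[idx]
  }
  alt <- matrix(tabulate(base_idx[keep] + 4L * (cpos - 1L), nbins = 4L * L),
                nrow = 4)
  cons_chars <- strsplit(consensus, "")[[1]]
  for (p in seq_len(L)) {
    if (ccov[p] == 0) next
    votes_ref <- ccov[p] - sum(alt[, p])
    best_alt <- which.max(alt[, p])
    if (alt[best_alt, p] > votes_ref) cons_chars[p] <- DNA_BASES[best_alt]
  }
  paste(cons_chars, collapse = "")
}

#' Group cluster consensuses into families and subfamilies
#'
#' Single-linkage grouping: two cluster consensuses belong to one family when
#' a rotation-aware local alignment covers at least `min_coverage` of the
#' shorter sequence at `min_identity` or better.  Each retained cluster
#' consensus becomes one subfamily of its family; the result is
#' order-invariant in the input.
#'
#' @param consensuses Tibble with columns `cluster` and `consensus` (one row
#'   per cluster), or a character vector.
#' @param min_identity Identity threshold (default 0.8).
#' @param min_coverage Coverage-of-shorter threshold (default 0.5).
#' @return The input tibble with a `family_group` integer column; groups are
#'   numbered in input order of their first member.
#' @export
assign_subfamilies <- function(consensuses, min_identity = 0.8,
                               min_coverage = 0.5) {
  if (is.character(consensuses)) {
    consensuses <- tibble(cluster = paste0("CL", seq_along(consensuses)),
                          consensus = consensuses)
  }
  n <- nrow(consensuses)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (n > 1) {
    edges <- integer(0)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        hit <- aligned_similarity(consensuses$consensus[i],
                                  consensuses$consensus[j])
        if (hit$coverage_short >= min_coverage && hit$identity >= min_identity) {
          edges <- c(edges, i, j)
        }
      }
    }
    if (length(edges)) g <- igraph::add_edges(g, edges)
  }
  comp <- igraph::components(g)$membership
  mutate(consensuses, family_group = as.integer(comp))
}

## Best rotation-aware local alignment between two consensuses; the shorter
## sequence is doubled so junction-spanning similarity is visible, and both
## strands are tried.  Returns identity (matches / aligned columns) and
## coverage of the shorter monomer.
aligned_similarity <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  short_len <- nchar(a)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  pats <- Biostrings::DNAStringSet(c(strrep(a, 2), revcomp(strrep(a, 2))))
  aln <- Biostrings::pairwiseAlignment(pats, Biostrings::DNAString(b),
                                       type = "local", substitutionMatrix = mat,
                                       gapOpening = 5, gapExtension = 2)
  best <- which.max(Biostrings::score(aln))
  a1 <- strsplit(as.character(Biostrings::alignedPattern(aln[best])), "")[[1]]
  a2 <- strsplit(as.character(Biostrings::alignedSubject(aln[best])), "")[[1]]
  ncol_aln <- length(a1)
  matches <- sum(a1 == a2 & a1 != "-")
  pat_cols <- sum(a1 != "-")
  list(identity = if (ncol_aln > 0) matches / ncol_aln else 0,
       coverage_short = min(1, pat_cols / short_len),
       aln_length = ncol_aln,
       score = Biostrings::score(aln)[best])
}

#' Name satellite families by abundance rank and monomer length
#'
#' Names follow the convention `<prefix>Sat<rank>-<length>`: a species
#' abbreviation, a zero-padded rank in decreasing genome proportion, and the
#' consensus length in bp (e.g. rank 1 at 165 bp under prefix "Rpro" is
#' "RproSat01-165").  Ties in proportion break by decreasing length, then by
#' lexicographic consensus.
#'
#' @param families Tibble with columns `consensus` and `proportion` (genome
#'   proportion, any common scale).
#' @param prefix Species abbreviation, e.g. a 4-letter code like "Rpro".
#' @return The tibble sorted by rank with `rank` and `name` columns added.
#' @export
name_families <- function(families, prefix = "Rpro") {
  families |>
    mutate(.len = nchar(.data$consensus)) |>
    arrange(desc(.data$proportion), desc(.data$.len), .data$consensus) |>
    mutate(rank = row_number(),
           name = sprintf("%sSat%02d-%d", prefix, .data$rank, .data$.len)) |>
    select(-".len")
}

#' Build an alignment reference from a consensus
#'
#' Tandem copies of the consensus so the reference holds at least two
#' monomers and about 200 bp: the consensus is repeated
#' `max(2, ceiling(200 / length))` times.  Short declared motifs (e.g. the
#' telomeric TTAGG) get many copies by the same rule.
#'
#' @param consensus DNA string (>= 4 bp for discovered families; short
#'   motifs of any length >= 2 are accepted via `allow_short`).
#' @param target_bp Reference length target (default 200).
#' @param allow_short Accept consensus shorter than 4 bp (declared motifs).
#' @return The reference DNA string.
#' @export
#' @examples
#' nchar(build_reference(strrep("A", 165)))  # 330: a dimer
#' nchar(build_reference(strrep("A", 31)))   # 217: 7 copies
build_reference <- function(consensus, target_bp = 200, allow_short = FALSE) {
  L <- nchar(consensus)
  if (L < 4 && !allow_short) abort("Consensus must be >= 4 bp.")
  copies <- max(2, ceiling(target_bp / L))
  strrep(consensus, copies)
}

#' Declare a short-motif satellite (telomeric or microsatellite)
#'
#' Low-complexity motifs such as (TTAGG)n or (GATA)n escape graph-based
#' discovery; they are declared explicitly and quantified with references
#' built by the same concatenation rule as discovered families.
#'
#' @param name Label, e.g. "telomeric".
#' @param motif Repeat unit, e.g. "TTAGG".
#' @return A one-row tibble with `family`, `consensus`, `reference`.
#' @export
declare_motif_family <- function(name, motif) {
  tibble(family = name, consensus = motif,
         reference = build_reference(motif, allow_short = TRUE))
}
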
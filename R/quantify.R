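# RepeatMasker-style quantification: seeded local alignment of sampled reads
# against the family reference collection, per-base overlap resolution,
# genome-proportion and Kimura-2P divergence estimates, repeat landscapes,
# and the family-table summary statistics.

#' Kimura 2-parameter distance
#'
#' `K = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))` with `P` the transition and
#' `Q` the transversion proportion over aligned (gap-free) columns.
#' Vectorized; returns `NA` where the distance is undefined
#' (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`).
#'
#' @param P,Q Transition and transversion proportions (`P, Q >= 0`,
#'   `P + Q <= 1`), recycled to a common length.
#' @return Numeric vector of distances (substitutions per site).
#' @export
#' @examples
#' kimura2p(0.1, 0.05)
kimura2p <- function(P, Q) {
  if (any(P < 0 | Q < 0, na.rm = TRUE)) abort("P and Q must be >= 0.")
  if (any(P + Q > 1 + 1e-12, na.rm = TRUE)) abort("P + Q must be <= 1.")
  a <- 1 - 2 * P - Q
  b <- 1 - 2 * Q
  ifelse(a > 0 & b > 0, -0.5 * log(a * sqrt(b)), NA_real_)
}

#' Align reads against the satellite reference collection
#'
#' Seeded (shared k-mer) gapped local alignment of every read against every
#' reference, on both strands.  Scoring is +1 match / -1 mismatch with affine
#' gaps (open 5, extend 2), so `min_score` is roughly a matched-bp
#' equivalent.  Per hit, transition (`P`) and transversion (`Q`) proportions
#' are counted over gap-free aligned columns and converted to a Kimura-2P
#' distance `K`.
#'
#' @param reads Read tibble (`id`, `seq`).
#' @param references Tibble with `family` and `reference` columns (one row
#'   per family or subfamily reference).
#' @param min_score Minimum alignment score to keep a hit (default 30).
#' @param seed_k Seeding k-mer size (default 11); a read/reference pair is
#'   aligned only when it shares at least one canonical `seed_k`-mer.
#' @return A hit tibble: `read`, `family`, `start`, `end` (0-based half-open
#'   on the read), `matched_cols`, `P`, `Q`, `K`, `score`, `strand`.
#' @export
map_reads <- function(reads, references, min_score = 30, seed_k = 11) {
  if (nrow(references) == 0) abort("Reference set is empty.")
  if (!all(c("family", "reference") %in% names(references))) {
    abort("`references` needs `family` and `reference` columns.")
  }
  nr <- nrow(reads)
  read_km <- canonical_kmers(reads$seq, seed_k)
  ref_km <- canonical_kmers(references$reference, seed_k)
  cand <- dplyr::inner_join(read_km, ref_km, by = "kmer",
                            relationship = "many-to-many",
                            suffix = c("_q", "_r")) |>
    distinct(read = .data$read_q, ref = .data$read_r)
  if (nrow(cand) == 0) {
    return(empty_hits())
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  hits <- vector("list", 2 * nrow(references))
  hi <- 0
  for (ri in sort(unique(cand$ref))) {
    ridx <- cand$read[cand$ref == ri]
    pats <- Biostrings::DNAStringSet(reads$seq[ridx])
    for (strand in c("+", "-")) {
      ref_seq <- references$reference[ri]
      if (strand == "-") ref_seq <- revcomp(ref_seq)
      aln <- Biostrings::pairwiseAlignment(
        pats, Biostrings::DNAString(ref_seq), type = "local",
        substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
      sc <- Biostrings::score(aln)
      keep <- which(sc >= min_score)
      if (!length(keep)) next
      sub <- aln[keep]
      # transition/transversion counts from the vectorized mismatch table;
      # matched_cols = gap-free aligned columns
      matched <- Biostrings::nmatch(sub) + Biostrings::nmismatch(sub)
      mm <- Biostrings::mismatchTable(sub)
      pu <- function(b) b == "A" | b == "G"
      is_ts <- pu(as.character(mm$PatternSubstring)) ==
        pu(as.character(mm$SubjectSubstring))
      ts <- tabulate(mm$PatternId[is_ts], nbins = length(keep))
      tv <- tabulate(mm$PatternId[!is_ts], nbins = length(keep))
      pr <- Biostrings::pattern(sub)@range
      hi <- hi + 1
      hits[[hi]] <- tibble(
        read = reads$id[ridx[keep]],
        family = references$family[ri],
        start = pr@start - 1L, end = pr@start + pr@width - 1L,
        matched_cols = as.integer(matched),
        P = ifelse(matched > 0, ts / matched, 0),
        Q = ifelse(matched > 0, tv / matched, 0),
        score = sc[keep], strand = strand)
    }
  }
  if (hi == 0) return(empty_hits())
  out <- bind_rows(hits[seq_len(hi)])
  # one strand per (read, reference): keep the better-scoring orientation
  out <- out |>
    arrange(.data$read, .data$family, desc(.data$score), .data$strand) |>
    distinct(.data$read, .data$family, .keep_all = TRUE) |>
    mutate(K = kimura2p(.data$P, .data$Q)) |>
    select("read", "family", "start", "end", "matched_cols",
           "P", "Q", "K", "score", "strand")
  arrange(out, .data$read, desc(.data$score))
}

empty_hits <- function() {
  tibble(read = character(), family = character(), start = integer(),
         end = integer(), matched_cols = integer(), P = double(),
         Q = double(), K = double(), score = double(), strand = character())
}

#' Resolve overlapping hits on each read
#'
#' RepeatMasker-style greedy masking: per read, hits are taken in order of
#' decreasing score; a hit is kept only when it overlaps every already-kept
#' hit by fewer than `max_overlap` bp, and kept hits are trimmed so that each
#' read base is masked at most once.
#'
#' @param hits Hit tibble from [map_reads()].
#' @param max_overlap A candidate overlapping a kept hit by this many bp or
#'   more is dropped (default 10).
#' @return The kept, trimmed hit tibble (columns as input).
#' @export
resolve_overlaps <- function(hits, max_overlap = 10) {
  if (nrow(hits) == 0) return(hits)
  multi_reads <- unique(hits$read[duplicated(hits$read)])
  single <- filter(hits, !(.data$read %in% multi_reads))
  multi <- filter(hits, .data$read %in% multi_reads)
  if (nrow(multi)) {
    multi <- multi |>
      group_by(.data$read) |>
      dplyr::group_modify(~ resolve_one_read(.x, max_overlap)) |>
      ungroup()
  }
  arrange(bind_rows(single, multi), .data$read, .data$start)
}

resolve_one_read <- function(h, max_overlap) {
  h <- arrange(h, desc(.data$score), .data$start, .data$family)
  kept <- h[0, , drop = FALSE]
  for (i in seq_len(nrow(h))) {
    s <- h$start[i]; e <- h$end[i]
    if (nrow(kept)) {
      ov <- pmax(0, pmin(e, kept$end) - pmax(s, kept$start))
      if (any(ov >= max_overlap)) next
      # trim residual overlap off the candidate
      for (j in which(ov > 0)) {
        ks <- kept$start[j]; ke <- kept$end[j]
        if (s < ks && e > ks) e <- ks
        else if (s < ke && e > ke) s <- ke
        else if (s >= ks && e <= ke) { s <- e <- 0L; break }
      }
      if (e - s <= 0) next
    }
    row <- h[i, , drop = FALSE]
    row$start <- as.integer(s); row$end <- as.integer(e)
    kept <- bind_rows(kept, row)
  }
  arrange(kept, .data$start)
}

#' Per-family genome proportion from resolved hits
#'
#' Proportion = masked bp assigned to the family / total sampled bp.  When a
#' `family_of` mapping is supplied (subfamily -> family), subfamily masked bp
#' is also rolled up so that subfamily bp sums to family bp.
#'
#' @param hits Resolved hit tibble.
#' @param total_bp Total sampled read bp.
#' @param family_of Optional named character vector mapping reference name to
#'   parent family.
#' @return Tibble `family`, `masked_bp`, `proportion`.
#' @export
family_abundance <- function(hits, total_bp, family_of = NULL) {
  tb <- hits |>
    mutate(family = if (is.null(family_of)) .data$family
           else unname(family_of[.data$family])) |>
    group_by(family = .data$family) |>
    summarise(masked_bp = sum(.data$end - .data$start), .groups = "drop") |>
    mutate(proportion = .data$masked_bp / total_bp) |>
    arrange(desc(.data$masked_bp))
  tb
}

#' Per-family mean Kimura divergence
#'
#' Mean of per-hit `K` weighted by matched columns, as a percentage.  Hits
#' with undefined `K` contribute to abundance but are excluded here; a family
#' with no defined-`K` hit reports `NA`.
#'
#' @param hits Resolved hit tibble.
#' @param family_of Optional subfamily -> family mapping as in
#'   [family_abundance()].
#' @return Tibble `family`, `divergence_pct`, `n_hits`.
#' @export
family_divergence <- function(hits, family_of = NULL) {
  hits |>
    mutate(family = if (is.null(family_of)) .data$family
           else unname(family_of[.data$family])) |>
    group_by(family = .data$family) |>
    summarise(
      divergence_pct = if (any(!is.na(.data$K))) {
        100 * sum(.data$K * .data$matched_cols, na.rm = TRUE) /
          sum(.data$matched_cols[!is.na(.data$K)])
      } else NA_real_,
      n_hits = dplyr::n(), .groups = "drop")
}

#' Repeat landscape: masked bp by divergence bin
#'
#' Bins each hit's masked bp by `floor(100 * K)` into 1-percentage-point
#' divergence bins `[i, i+1)`, capped at `[49, 50)`, the RepeatMasker
#' landscape convention.  Undefined-`K` hits are excluded.
#'
#' @param hits Resolved hit tibble.
#' @param total_bp Total sampled bp (for the percent-of-genome column).
#' @param family_of Optional subfamily -> family mapping.
#' @return Long tibble `family`, `bin_low`, `bin_high`, `bp`, `pct_genome`,
#'   of class `satkit_landscape`.
#' @export
landscape <- function(hits, total_bp, family_of = NULL) {
  out <- hits |>
    filter(!is.na(.data$K)) |>
    mutate(family = if (is.null(family_of)) .data$family
           else unname(family_of[.data$family]),
           bin_low = pmin(floor(100 * .data$K), 49)) |>
    group_by(.data$family, .data$bin_low) |>
    summarise(bp = sum(.data$end - .data$start), .groups = "drop") |>
    mutate(bin_high = .data$bin_low + 1,
           pct_genome = 100 * .data$bp / total_bp) |>
    select("family", "bin_low", "bin_high", "bp", "pct_genome")
  class(out) <- c("satkit_landscape", class(out))
  out
}

#' Summary statistics of a satellite family table
#'
#' Mean, sample standard deviation (n-1 denominator) and median of the
#' repeat-unit length, A+T percentage and divergence columns, plus the summed
#' genome proportion, computed over all rows (declared short-motif rows
#' included).
#'
#' @param families Family table with columns `length_bp`, `at_pct`,
#'   `divergence_pct`, `proportion_pct` (as from [load_family_table()]).
#' @return A `satkit_summary` tibble with rows Mean, SD, Median and the total
#'   proportion in the `proportion_pct` column of the Total row.
#' @export
summarize_table <- function(families) {
  need <- c("length_bp", "at_pct", "divergence_pct", "proportion_pct")
  if (!all(need %in% names(families))) {
    abort(paste("Family table must have columns:", paste(need, collapse = ", ")))
  }
  n <- nrow(families)
  if (n < 2) warn("Fewer than 2 rows: SD is not available.")
  stat_row <- function(label, f) {
    tibble(statistic = label,
           length_bp = f(families$length_bp),
           at_pct = f(families$at_pct),
           divergence_pct = f(families$divergence_pct),
           proportion_pct = NA_real_)
  }
  out <- bind_rows(
    stat_row("Mean", mean),
    stat_row("SD", function(x) if (n >= 2) sd(x) else NA_real_),
    stat_row("Median", median),
    tibble(statistic = "Total", length_bp = NA_real_, at_pct = NA_real_,
           divergence_pct = NA_real_,
           proportion_pct = sum(families$proportion_pct))
  )
  class(out) <- c("satkit_summary", class(out))
  out
}

#' @export
print.satkit_summary <- function(x, digits = 2, ...) {
  y <- mutate(as_tibble(x), across(dplyr::where(is.numeric), ~ round(.x, digits)))
  print(y, ...)
  invisible(x)
}
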
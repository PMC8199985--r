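# Satellite transcription: count RNA-seq reads per family against the same
# dimer/concatenation references used for genomic quantification, CPM
# normalization, the >50-CPM-in->=2-samples expression filter, dominance
# classification into the four tissue patterns, and the transcription ~
# genomic-abundance Spearman correlation.

#' Count RNA-seq reads per satellite family
#'
#' Each read is aligned (seeded local alignment, both strands) against every
#' family reference; it increments exactly one family — the best alignment
#' score, ties going to the lexicographically first family name.  Reads with
#' no alignment at `min_score` count toward a `"background"` bucket standing
#' in for the non-satellite transcriptome.
#'
#' @param reads Read tibble (`id`, `seq`), e.g. one [sim_rnaseq()] sample.
#' @param references Tibble with `family` and `reference` columns (the
#'   [build_reference()] collection).
#' @param min_score Minimum alignment score (default 30).
#' @return Tibble `family`, `count`, including the `background` row; every
#'   reference family appears (zero counts kept).
#' @export
count_rna_reads <- function(reads, references, min_score = 30) {
  if (nrow(reads) == 0) abort("Sample is empty.")
  hits <- map_reads(reads, references, min_score = min_score)
  best <- hits |>
    arrange(.data$read, desc(.data$score), .data$family) |>
    distinct(.data$read, .keep_all = TRUE)
  counted <- count(best, family = .data$family, name = "count")
  all_fams <- tibble(family = references$family)
  out <- left_join(all_fams, counted, by = "family") |>
    mutate(count = tidyr::replace_na(.data$count, 0L))
  bind_rows(out, tibble(family = "background",
                        count = nrow(reads) - sum(out$count)))
}

#' CPM-normalize a count matrix
#'
#' Counts per million: `count / total_counted_reads * 1e6` per sample, the
#' total taken over all counted features (families plus the background
#' bucket), so CPM columns sum to 1e6.
#'
#' @param counts Tibble with a `family` column and one numeric column per
#'   sample.
#' @return Tibble of the same shape with CPM values.
#' @export
cpm_normalize <- function(counts) {
  num_cols <- names(counts)[vapply(counts, is.numeric, logical(1))]
  totals <- vapply(counts[num_cols], sum, numeric(1))
  if (any(totals <= 0)) abort("Every sample must have a positive total count.")
  mutate(counts, across(dplyr::all_of(num_cols), ~ .x / sum(.x) * 1e6))
}

#' Filter families by expression
#'
#' Retains a family iff its CPM exceeds `min_cpm` (strictly) in at least
#' `min_samples` samples.
#'
#' @param cpm CPM tibble from [cpm_normalize()] (`family` column + numeric
#'   sample columns).
#' @param min_cpm Strict CPM threshold (default 50).
#' @param min_samples Minimum number of qualifying samples (default 2).
#' @return The input with a logical `retained` column.
#' @export
filter_expressed <- function(cpm, min_cpm = 50, min_samples = 2) {
  num_cols <- names(cpm)[vapply(cpm, is.numeric, logical(1))]
  if (length(num_cols) < min_samples) abort("Need at least `min_samples` sample columns.")
  qualifying <- rowSums(as.matrix(cpm[num_cols]) > min_cpm)
  mutate(cpm, retained = qualifying >= min_samples)
}

#' Classify a family's tissue transcription pattern
#'
#' Four qualitative patterns quantified by a dominance threshold on
#' tissue-group mean CPM (antenna `a`, ovary `o`, testis `t`, total `T`):
#' \describe{
#'   \item{P2 antenna-biased}{`a/T >= dominance`}
#'   \item{P4 single-gonad}{`o/T >= dominance` or `t/T >= dominance`}
#'   \item{P3 gonad-biased}{`(o+t)/T >= dominance`, neither gonad alone
#'     dominant}
#'   \item{P1 ubiquitous}{otherwise}
#' }
#'
#' @param a,o,t Non-negative group means (vectors recycled to common length).
#' @param dominance Dominance threshold (default 0.7).
#' @return Character vector in `c("P1","P2","P3","P4")`; `NA` when all three
#'   means are zero.
#' @export
classify_pattern <- function(a, o, t, dominance = 0.7) {
  if (any(c(a, o, t) < 0)) abort("Group means must be >= 0.")
  total <- a + o + t
  dplyr::case_when(
    total == 0 ~ NA_character_,
    a / total >= dominance ~ "P2",
    o / total >= dominance | t / total >= dominance ~ "P4",
    (o + t) / total >= dominance ~ "P3",
    TRUE ~ "P1"
  )
}

#' Expression-pattern table across tissue groups
#'
#' Convenience wrapper: CPM-normalize, filter, average sample columns into
#' tissue groups and classify retained families.
#'
#' @param counts Count tibble (`family` + one column per sample).
#' @param groups Named list mapping group names `antenna`, `ovary`, `testis`
#'   to character vectors of sample column names.
#' @param min_cpm,min_samples Filter parameters (see [filter_expressed()]).
#' @param dominance Dominance threshold (see [classify_pattern()]).
#' @return Tibble `family`, group means, `retained`, `pattern` (NA for
#'   dropped families and for the background bucket).
#' @export
expression_patterns <- function(counts, groups, min_cpm = 50, min_samples = 2,
                                dominance = 0.7) {
  stopifnot(all(c("antenna", "ovary", "testis") %in% names(groups)))
  cpm <- cpm_normalize(counts)
  flt <- filter_expressed(cpm, min_cpm, min_samples)
  gm <- function(cols) rowMeans(as.matrix(flt[, cols, drop = FALSE]))
  out <- tibble(
    family = flt$family,
    antenna = gm(groups$antenna),
    ovary = gm(groups$ovary),
    testis = gm(groups$testis),
    retained = flt$retained & flt$family != "background")
  mutate(out, pattern = ifelse(
    .data$retained,
    classify_pattern(.data$antenna, .data$ovary, .data$testis, dominance),
    NA_character_))
}

#' Correlate satellite transcription with genomic abundance
#'
#' Spearman rank correlation (average ranks for ties) between a per-family
#' transcription summary (by default the mean CPM over all samples) and the
#' genomic proportion.  The two-sided p-value uses the exact permutation
#' distribution for n <= 9 without ties and the t approximation otherwise.
#'
#' @param transcription Numeric vector (e.g. mean CPM per family).
#' @param abundance Numeric vector of genome proportions, same length/order.
#' @return A `satkit_correlation` object (list with `r_s`, `p_value`, `n`,
#'   `method`).
#' @export
correlate_abundance <- function(transcription, abundance) {
  ok <- is.finite(transcription) & is.finite(abundance)
  x <- transcription[ok]; y <- abundance[ok]
  n <- length(x)
  if (n < 5) abort("Need at least 5 families for the correlation.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation is not available for a constant vector.")
  }
  rx <- rank(x); ry <- rank(y)
  r_s <- cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 9 && !ties) {
    ct <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
    p <- ct$p.value
    method <- "exact"
  } else {
    tstat <- r_s * sqrt((n - 2) / (1 - r_s^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  }
  structure(list(r_s = r_s, p_value = p, n = n, method = method),
            class = "satkit_correlation")
}

#' @export
print.satkit_correlation <- function(x, ...) {
  cat(sprintf("Spearman r_s = %.3f, p = %.4g (n = %d, %s)\n",
              x$r_s, x$p_value, x$n, x$method))
  invisible(x)
}
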
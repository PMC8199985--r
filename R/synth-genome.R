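# Synthetic satellitomes: consensus monomers, mutated copies, genomes with
# machine-readable array truth.  All generators are pure functions of
# (arguments, seed).

#' Generate a random consensus monomer
#'
#' Draws an i.i.d. DNA sequence with a target A+T composition, the starting
#' point ("ancestral monomer") for a simulated satellite family.
#'
#' @param length Monomer length in bp (>= 4).
#' @param at_content Expected A+T fraction in `[0, 1]`.
#' @param seed Integer seed; same inputs give identical output.
#' @return A DNA string of the requested length.
#' @export
#' @examples
#' make_consensus(165, at_content = 0.72, seed = 7)
make_consensus <- function(length, at_content = 0.65, seed = 1) {
  if (length < 4) abort("`length` must be >= 4.")
  if (at_content < 0 || at_content > 1) abort("`at_content` must be in [0, 1].")
  with_seed(seed, random_dna(length, at_content))
}

## Vectorized mutation engine over a character vector of copies.
## Substitution per site with prob `divergence`; a substitution is a
## transition with prob ts_tv_ratio / (ts_tv_ratio + 1), otherwise one of the
## two transversions equiprobably.  Single-base indels at `indel_rate`,
## insertion/deletion equiprobable.  Returns the mutated copies with attribute
## "n_sub" (substituted sites) and "n_sites" (sites at risk).
mutate_seqs <- function(seqs, divergence, ts_tv_ratio = 2, indel_rate = 0) {
  if (divergence < 0 || divergence > 0.3) abort("`divergence` must be in [0, 0.3].")
  if (indel_rate < 0 || indel_rate > 0.05) abort("`indel_rate` must be in [0, 0.05].")
  if (ts_tv_ratio < 0) abort("`ts_tv_ratio` must be >= 0.")
  lens <- nchar(seqs)
  total <- sum(lens)
  if (total == 0) return(seqs)
  b <- utf8ToInt(paste(seqs, collapse = ""))
  code <- integer(length(b))
  code[b == 67L] <- 1L; code[b == 71L] <- 2L; code[b == 84L] <- 3L
  hit <- which(runif(total) < divergence)
  n_ts <- 0L
  if (length(hit)) {
    is_ts <- runif(length(hit)) < ts_tv_ratio / (ts_tv_ratio + 1)
    n_ts <- sum(is_ts)
    shift <- ifelse(is_ts, 2L, sample(c(1L, 3L), length(hit), replace = TRUE))
    code[hit] <- (code[hit] + shift) %% 4L
  }
  out_chars <- DNA_BASES[code + 1L]
  if (indel_rate > 0) {
    ind <- which(runif(total) < indel_rate)
    if (length(ind)) {
      del <- runif(length(ind)) < 0.5
      out_chars[ind[del]] <- ""
      ins <- ind[!del]
      if (length(ins)) {
        out_chars[ins] <- paste0(sample(DNA_BASES, length(ins), replace = TRUE),
                                 out_chars[ins])
      }
    }
  }
  ends <- cumsum(lens)
  starts <- c(1, head(ends, -1) + 1)
  res <- vapply(seq_along(seqs), function(i) {
    paste(out_chars[starts[i]:ends[i]], collapse = "")
  }, character(1))
  attr(res, "n_sub") <- length(hit)
  attr(res, "n_ts") <- n_ts
  attr(res, "n_sites") <- total
  res
}

#' Mutate one satellite copy away from its consensus
#'
#' Applies per-site substitutions with a transition/transversion bias and
#' optional single-base indels, the per-copy divergence model used by the
#' genome simulator.
#'
#' @param monomer DNA string to mutate.
#' @param divergence Per-site substitution probability in `[0, 0.3]`.
#' @param ts_tv_ratio Transitions-per-transversion bias (>= 0); a substitution
#'   is a transition with probability `ts_tv_ratio / (ts_tv_ratio + 1)`.
#' @param indel_rate Per-site probability of a single-base indel in
#'   `[0, 0.05]`; insertions and deletions are equiprobable.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is used.
#' @return The mutated DNA string.
#' @export
mutate_copy <- function(monomer, divergence, ts_tv_ratio = 2, indel_rate = 0,
                        seed = NULL) {
  run <- function() as.character(mutate_seqs(monomer, divergence, ts_tv_ratio, indel_rate))
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Specify satellite families for the genome simulator
#'
#' Builds the per-family specification table consumed by [build_genome()].
#' Each row describes one family (or one subfamily, via `subfamily_of`): its
#' consensus monomer, the fraction of the genome its arrays should occupy,
#' the expected per-copy divergence from the consensus and how many tandem
#' arrays the copies are split into.
#'
#' @param name Family labels.
#' @param monomer Consensus monomer DNA strings (30-1000 bp typical).
#' @param target_proportion Target genome fraction per family, each in
#'   `[0, 0.35]`, summing to at most 0.5.
#' @param divergence Expected per-copy substitution distance from the
#'   consensus, in `[0, 0.3]`.
#' @param ts_tv_ratio Transition/transversion bias (recycled).
#' @param indel_rate Per-site indel probability (recycled).
#' @param n_arrays Number of tandem arrays per family (recycled).
#' @param subfamily_of Optional parent family label (`NA` for top-level
#'   families); subfamilies occupy their own arrays, never mixed.
#' @return A `sat_family_spec` tibble.
#' @export
sat_family_spec <- function(name, monomer, target_proportion, divergence,
                            ts_tv_ratio = 2, indel_rate = 0, n_arrays = 1,
                            subfamily_of = NA_character_) {
  spec <- tibble(
    name = as.character(name), monomer = as.character(monomer),
    target_proportion = target_proportion, divergence = divergence,
    ts_tv_ratio = ts_tv_ratio, indel_rate = indel_rate,
    n_arrays = as.integer(n_arrays), subfamily_of = as.character(subfamily_of)
  )
  validate_family_spec(spec)
  spec
}

validate_family_spec <- function(spec) {
  if (nrow(spec) == 0) return(invisible(spec))
  if (any(!grepl("^[ACGT]+$", spec$monomer))) {
    abort("Monomers must be over the alphabet {A,C,G,T}.")
  }
  if (any(spec$target_proportion < 0 | spec$target_proportion > 0.35)) {
    abort("Each `target_proportion` must be in [0, 0.35].")
  }
  if (sum(spec$target_proportion) > 0.5) {
    abort("Total `target_proportion` over all families must be <= 0.5.")
  }
  if (any(spec$divergence < 0 | spec$divergence > 0.3)) {
    abort("`divergence` must be in [0, 0.3].")
  }
  if (any(spec$n_arrays < 1)) abort("`n_arrays` must be >= 1.")
  invisible(spec)
}

## Place `widths` non-overlapping intervals uniformly on [0, len); bounded
## rejection sampling.  Returns 0-based starts or aborts.
place_intervals <- function(widths, len, max_tries = 2000) {
  starts <- integer(0)
  placed_s <- integer(0); placed_e <- integer(0)
  for (w in widths) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      s <- sample.int(len - w + 1, 1) - 1L
      if (!any(s < placed_e & (s + w) > placed_s)) {
        placed_s <- c(placed_s, s); placed_e <- c(placed_e, s + w)
        starts <- c(starts, s)
        ok <- TRUE
        break
      }
    }
    if (!ok) abort("Could not place satellite arrays without overlap; reduce total proportion or array count.")
  }
  starts
}

#' Simulate a genome with planted satellite arrays
#'
#' Generates i.i.d. background sequence and plants, for every family row of
#' `specs`, `n_arrays` tandem arrays of independently mutated monomer copies
#' at random non-overlapping loci.  Subfamily rows get their own arrays, so a
#' single array never mixes two sequence variants.  The returned truth tables
#' are the ground-truth surface that downstream parameter-recovery tests
#' consume.
#'
#' @param specs A [sat_family_spec()] tibble.
#' @param genome_length Total genome length in bp (sum over scaffolds).
#' @param seed Integer seed.
#' @param scaffold_lengths Optional vector of scaffold lengths summing to
#'   `genome_length`; default is a single scaffold.
#' @param background_at A+T fraction of the background sequence (default 0.65).
#' @return An object of class `satkit_genome`: a list with
#'   \describe{
#'     \item{genome}{tibble `id`, `seq` (one row per scaffold)}
#'     \item{arrays}{truth tibble: `scaffold`, `start`, `end` (0-based
#'       half-open), `family`, `copies`, `divergence` (realized per-array,
#'       on the Kimura-2P scale the quantification stage estimates) and
#'       `p_distance` (raw substituted-site fraction)}
#'     \item{families}{per-family realized `proportion` and mean `divergence`}
#'   }
#' @export
build_genome <- function(specs, genome_length, seed = 1,
                         scaffold_lengths = NULL, background_at = 0.65) {
  validate_family_spec(specs)
  if (is.null(scaffold_lengths)) scaffold_lengths <- genome_length
  if (sum(scaffold_lengths) != genome_length) {
    abort("`scaffold_lengths` must sum to `genome_length`.")
  }
  with_seed(seed, {
    scaf_ids <- sprintf("scaffold_%03d", seq_along(scaffold_lengths))
    seqs <- vapply(scaffold_lengths, random_dna, character(1), at_content = background_at)

    arrays <- tibble(scaffold = character(), start = integer(), end = integer(),
                     family = character(), copies = integer(),
                     divergence = double(), p_distance = double())
    if (nrow(specs) > 0) {
      # build all array sequences first, then place them per scaffold
      art <- purrr::pmap_dfr(specs, function(name, monomer, target_proportion,
                                             divergence, ts_tv_ratio, indel_rate,
                                             n_arrays, subfamily_of) {
        mlen <- nchar(monomer)
        total_copies <- max(n_arrays, round(target_proportion * genome_length / mlen))
        per_array <- diff(round(seq(0, total_copies, length.out = n_arrays + 1)))
        per_array[per_array < 1] <- 1L
        purrr::map_dfr(per_array, function(nc) {
          mut <- mutate_seqs(rep(monomer, nc), divergence, ts_tv_ratio, indel_rate)
          sites <- attr(mut, "n_sites")
          p_real <- attr(mut, "n_ts") / sites
          q_real <- (attr(mut, "n_sub") - attr(mut, "n_ts")) / sites
          # realized divergence on the Kimura-2P scale (what the read-masking
          # stage estimates); the raw substituted-site fraction is kept too
          tibble(family = name, copies = as.integer(nc),
                 seq = paste(mut, collapse = ""),
                 divergence = kimura2p(p_real, q_real),
                 p_distance = p_real + q_real)
        })
      })
      # assign arrays to scaffolds proportional to length, then place
      art <- art[sample.int(nrow(art)), , drop = FALSE]
      scaf_of <- sample(seq_along(scaffold_lengths), nrow(art), replace = TRUE,
                        prob = scaffold_lengths)
      for (si in seq_along(scaffold_lengths)) {
        rows <- which(scaf_of == si)
        if (!length(rows)) next
        w <- nchar(art$seq[rows])
        if (sum(w) > scaffold_lengths[si]) {
          abort("Satellite arrays exceed scaffold length; increase genome size.")
        }
        starts <- place_intervals(w, scaffold_lengths[si])
        s <- seqs[si]
        for (j in seq_along(rows)) {
          substr(s, starts[j] + 1, starts[j] + w[j]) <- art$seq[rows[j]]
        }
        seqs[si] <- s
        arrays <- bind_rows(arrays, tibble(
          scaffold = scaf_ids[si], start = starts, end = starts + w,
          family = art$family[rows], copies = art$copies[rows],
          divergence = art$divergence[rows],
          p_distance = art$p_distance[rows]))
      }
      arrays <- arrange(arrays, .data$scaffold, .data$start)
    }

    fam <- arrays |>
      group_by(family = .data$family) |>
      summarise(
        proportion = sum(.data$end - .data$start) / genome_length,
        divergence = sum(.data$divergence * (.data$end - .data$start)) /
          sum(.data$end - .data$start),
        p_distance = sum(.data$p_distance * (.data$end - .data$start)) /
          sum(.data$end - .data$start),
        n_arrays = dplyr::n(), .groups = "drop")
    if (nrow(specs) > 0) {
      fam <- left_join(select(specs, "name", "monomer", "subfamily_of"), fam,
                       by = c(name = "family")) |>
        rename(family = "name")
    }

    structure(list(genome = tibble(id = scaf_ids, seq = unname(seqs)),
                   arrays = arrays, families = fam,
                   genome_length = genome_length, seed = seed),
              class = "satkit_genome")
  })
}

#' @export
print.satkit_genome <- function(x, ...) {
  cat(sprintf("<satkit_genome> %s bp in %d scaffold(s), %d planted array(s), %d famil(ies)\n",
              format(x$genome_length, big.mark = ","), nrow(x$genome),
              nrow(x$arrays), nrow(x$families)))
  if (nrow(x$families)) print(x$families, ...)
  invisible(x)
}

#' Write simulator truth files
#'
#' Writes the array truth as BED (0-based half-open; name = family, score =
#' copy count, strand ".") and the per-family truth as TSV.
#'
#' @param sim A `satkit_genome` from [build_genome()].
#' @param bed_path,tsv_path Output paths (`NULL` to skip either).
#' @return Invisibly, the paths written.
#' @export
write_truth <- function(sim, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- sim$arrays |>
      mutate(score = .data$copies, strand = ".") |>
      select("scaffold", "start", "end", name = "family", "score", "strand")
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    write_tsv_provenance(
      select(sim$families, "family", realized_proportion = "proportion",
             realized_divergence = "divergence"),
      tsv_path, provenance = list(tool = "satkit", seed = sim$seed))
  }
  invisible(c(bed_path, tsv_path))
}
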
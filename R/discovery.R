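# Repeat discovery: random read sampling, canonical k-mer sharing graph,
# connected-component clustering, cluster representatives and tandem calling
# by self-shift periodicity.  This stage is a documented, simplified stand-in
# for graph-based repeat clustering pipelines (RepeatExplorer/TAREAN-style):
# the similarity measure is shared canonical k-mers rather than read-overlap
# alignments, and tandemness is called from a representative's self-shift
# identity profile rather than graph topology or dot plots.

#' Randomly sample reads
#'
#' Uniform sampling without replacement of `n` reads from a read tibble, the
#' scale-reduction step before graph clustering.
#'
#' @param reads Read tibble (`id`, `seq`, ...) as from [sim_reads()] or
#'   [read_fastq_tbl()].
#' @param n Number of reads to keep (`n` <= available reads).
#' @param seed Integer seed.
#' @param by_pair When `TRUE` and a `pair` column is present, whole read
#'   pairs are sampled (`n/2` pairs) so that mates stay together; mate
#'   adjacency is exploited when building cluster representatives.
#' @return The sampled subset of `reads` (original row order preserved).
#' @export
sample_reads <- function(reads, n, seed = 1, by_pair = FALSE) {
  avail <- nrow(reads)
  if (n > avail) {
    abort(sprintf("Requested %d reads but only %d are available (short by %d).",
                  n, avail, n - avail))
  }
  if (n == avail) return(reads)
  with_seed(seed, {
    if (by_pair && "pair" %in% names(reads)) {
      pairs <- unique(reads$pair)
      keep_pairs <- sample(pairs, min(length(pairs), ceiling(n / 2)))
      reads[reads$pair %in% keep_pairs, , drop = FALSE]
    } else {
      keep <- sort(sample.int(avail, n))
      reads[keep, , drop = FALSE]
    }
  })
}

## Contiguous insert sequence for the pair holding `read_id`: mate 1 followed
## by the reverse complement of mate 2 (the standard FR layout).  Falls back
## to the read itself when the mate is absent or the tibble has no pair info.
join_mate_pair <- function(read_id, reads) {
  if (!all(c("pair", "mate") %in% names(reads))) {
    return(reads$seq[match(read_id, reads$id)])
  }
  p <- reads$pair[match(read_id, reads$id)]
  rows <- reads[reads$pair == p, , drop = FALSE]
  if (nrow(rows) != 2) return(reads$seq[match(read_id, reads$id)])
  paste0(rows$seq[rows$mate == 1], revcomp(rows$seq[rows$mate == 2]))
}

## Mate-joined insert units for a set of member read ids (one unit per pair,
## deduplicated).  Units roughly double the contiguous sequence each cluster
## member contributes, which is what lets representatives of long monomers
## grow past twice the period.
## Precompute the pair -> joined-insert lookup for a read tibble.
unit_lookup <- function(reads) {
  if (!all(c("pair", "mate") %in% names(reads))) return(NULL)
  m1 <- reads[reads$mate == 1, c("pair", "seq")]
  m2 <- reads[reads$mate == 2, c("pair", "seq")]
  both <- dplyr::inner_join(m1, m2, by = "pair", suffix = c("_1", "_2"))
  units <- setNames(paste0(both$seq_1, revcomp(both$seq_2)), both$pair)
  # pairs with a single sampled mate fall back to that read
  lone <- setdiff(reads$pair, both$pair)
  if (length(lone)) {
    units <- c(units, setNames(reads$seq[match(lone, reads$pair)], lone))
  }
  units
}

cluster_units <- function(member_ids, reads, units = NULL) {
  if (is.null(units)) {
    return(unname(reads$seq[match(member_ids, reads$id)]))
  }
  pairs <- unique(reads$pair[match(member_ids, reads$id)])
  unname(units[pairs])
}

#' Build the k-mer sharing graph over reads
#'
#' Nodes are reads; an edge joins two reads sharing at least `min_shared`
#' canonical k-mers (a k-mer and its reverse complement count as one, so the
#' graph is strand-insensitive).
#'
#' @param reads Read tibble with `id` and `seq` columns.
#' @param k Odd k-mer size between 11 and 25.  The default 13 balances
#'   sensitivity to diverged satellite copies against random collisions at
#'   read scale; see the package vignette.
#' @param min_shared Minimum number of shared canonical k-mers for an edge
#'   (default 3).
#' @return An `igraph` graph with vertex attributes `name` (read id) and `bp`
#'   (read length) and edge attribute `shared`.
#' @export
build_kmer_graph <- function(reads, k = 13, min_shared = 3) {
  if (k %% 2 == 0 || k < 11 || k > 25) {
    abort("`k` must be odd and between 11 and 25.")
  }
  n <- nrow(reads)
  km <- canonical_kmers(reads$seq, k)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- reads$id
  igraph::V(g)$bp <- nchar(reads$seq)
  if (nrow(km) == 0) return(g)
  # sparse read x kmer incidence; shared-kmer counts via cross-product
  kid <- match(km$kmer, unique(km$kmer))
  M <- Matrix::sparseMatrix(i = km$read, j = kid, x = 1,
                            dims = c(n, max(kid)))
  A <- Matrix::tcrossprod(M)
  A <- methods::as(Matrix::triu(A, k = 1), "TsparseMatrix")
  sel <- A@x >= min_shared
  if (any(sel)) {
    g <- igraph::add_edges(g, rbind(A@i[sel] + 1L, A@j[sel] + 1L),
                           shared = A@x[sel])
  }
  g
}

#' Cluster reads into repeat clusters
#'
#' Connected components of the k-mer sharing graph become clusters, ranked by
#' total member bp and labelled CL1, CL2, ... in decreasing size.  Clusters
#' whose genome-proportion estimate (member bp / total sampled bp) falls below
#' `min_proportion` are discarded; discarded bp is accounted for in the
#' `dropped_bp` attribute so bp is conserved.
#'
#' @param graph Graph from [build_kmer_graph()].
#' @param total_bp Total sampled bp (denominator of the proportion estimate);
#'   defaults to the summed `bp` vertex attribute.
#' @param min_proportion Discard clusters below this genome proportion
#'   (default 1e-5, i.e. 0.001% of the genome).
#' @param reads Optional read tibble to attach member sequences (needed by
#'   [cluster_representative()] and downstream consensus building).
#' @param method `"components"` takes connected components; `"louvain"`
#'   (weighted Louvain community detection) additionally cuts the thin
#'   bridges that junction reads and chance overlaps create between repeat
#'   families at higher sampled coverage — within-family edges share tens of
#'   k-mers while bridges share close to `min_shared`.
#' @return A tibble with one row per retained cluster: `cluster`, `n_reads`,
#'   `bp`, `proportion`, `members` (list of read ids), `member_seqs` (list,
#'   if `reads` given), `seed_read` (highest-degree member).  Attribute
#'   `dropped_bp` holds the bp total of discarded clusters.
#' @export
cluster_reads <- function(graph, total_bp = NULL, min_proportion = 1e-5,
                          reads = NULL,
                          method = c("components", "louvain")) {
  method <- match.arg(method)
  membership <- if (method == "louvain" && igraph::ecount(graph) > 0) {
    igraph::membership(igraph::cluster_louvain(
      graph, weights = igraph::E(graph)$shared))
  } else {
    igraph::components(graph)$membership
  }
  bp <- igraph::V(graph)$bp
  ids <- igraph::V(graph)$name
  deg <- igraph::degree(graph)
  total_bp <- total_bp %||% sum(bp)
  tb <- tibble(id = ids, bp = bp, comp = as.integer(membership), degree = deg)
  cl <- tb |>
    group_by(comp = .data$comp) |>
    summarise(n_reads = dplyr::n(), bp = sum(.data$bp),
              first_id = min(.data$id),
              members = list(.data$id),
              seed_read = .data$id[which.max(.data$degree)],
              seed_candidates = list(.data$id[order(-.data$degree)][
                seq_len(min(5, dplyr::n()))]),
              .groups = "drop") |>
    arrange(desc(.data$bp), .data$first_id) |>
    mutate(cluster = paste0("CL", row_number()),
           proportion = .data$bp / total_bp)
  dropped <- filter(cl, .data$proportion < min_proportion)
  cl <- filter(cl, .data$proportion >= min_proportion) |>
    select("cluster", "n_reads", "bp", "proportion", "members", "seed_read",
           "seed_candidates")
  if (!is.null(reads)) {
    lookup <- setNames(reads$seq, reads$id)
    cl$member_seqs <- lapply(cl$members, function(m) unname(lookup[m]))
  }
  attr(cl, "dropped_bp") <- sum(dropped$bp)
  attr(cl, "n_dropped") <- nrow(dropped)
  attr(cl, "total_bp") <- total_bp
  cl
}

## Build a polished representative for one cluster.  Seed = highest-degree
## member; members are locally aligned to the current representative, a
## majority base is taken per representative column, and the representative
## is extended by the best-scoring overhanging member tail, iterating until
## no extension is possible or `max_len` is reached.
cluster_representative <- function(member_seqs, seed_seq = NULL,
                                   max_members = 80, rounds = 16,
                                   max_len = NULL, min_tail = 15) {
  n <- length(member_seqs)
  if (is.null(max_len)) max_len <- 3 * max(nchar(member_seqs))
  if (is.null(seed_seq)) seed_seq <- member_seqs[[which.max(nchar(member_seqs))]]
  if (n <= 1) return(seed_seq)
  if (n > max_members) {
    member_seqs <- member_seqs[round(seq(1, n, length.out = max_members))]
  }
  rep_seq <- seed_seq
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  # orient members to the seed: clustering is strand-canonical, so roughly
  # half the members arrive as reverse complements
  fw <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(member_seqs), Biostrings::DNAString(rep_seq),
    type = "local", substitutionMatrix = mat, gapOpening = 5, gapExtension = 2,
    scoreOnly = TRUE)
  rc_seqs <- revcomp(member_seqs)
  rv <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(rc_seqs), Biostrings::DNAString(rep_seq),
    type = "local", substitutionMatrix = mat, gapOpening = 5, gapExtension = 2,
    scoreOnly = TRUE)
  member_seqs <- ifelse(rv > fw, rc_seqs, member_seqs)
  for (round in seq_len(rounds)) {
    subj <- Biostrings::DNAString(rep_seq)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(member_seqs), subj, type = "local",
      substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
    ok <- Biostrings::score(aln) >= 20
    if (!any(ok)) break
    ap <- as.character(Biostrings::alignedPattern(aln[ok]))
    as_ <- as.character(Biostrings::alignedSubject(aln[ok]))
    sr <- Biostrings::subject(aln[ok])@range
    L <- nchar(rep_seq)
    alphabet <- c(DNA_BASES, "-")
    all_idx <- integer(0); all_pos <- integer(0)
    for (i in seq_along(ap)) {
      pa <- strsplit(ap[i], "")[[1]]
      sa <- strsplit(as_[i], "")[[1]]
      keep <- sa != "-"               # columns that exist in rep coordinates
      pos <- seq(sr@start[i], length.out = sum(keep))
      idx <- match(pa[keep], alphabet)
      valid <- !is.na(idx)
      all_idx <- c(all_idx, idx[valid]); all_pos <- c(all_pos, pos[valid])
    }
    counts <- matrix(tabulate(all_idx + 5L * (all_pos - 1L), nbins = 5L * L),
                     nrow = 5, dimnames = list(alphabet, NULL))
    covered <- colSums(counts) > 0
    best <- rownames(counts)[apply(counts, 2, which.max)]
    new <- strsplit(rep_seq, "")[[1]]
    repl <- covered & best != "-"
    new[repl] <- best[repl]
    new_rep <- paste(new, collapse = "")
    # extension: best-scoring member whose alignment reaches an end of rep
    # and whose overhanging tail cross-validates against other members
    # (junction reads carry background tails that would otherwise be grafted)
    pr <- Biostrings::pattern(aln)@range
    sr_all <- Biostrings::subject(aln)@range
    sc <- Biostrings::score(aln)
    mlen <- nchar(member_seqs)
    right_tail <- mlen - pr@start - pr@width + 1
    cand_r <- which(ok & sc >= 30 & sr_all@start + sr_all@width - 1 >= L - 2 &
                      right_tail >= min_tail)
    if (length(cand_r) && nchar(new_rep) < max_len) {
      for (i in cand_r[order(-sc[cand_r])]) {
        tail_seq <- substr(member_seqs[i], pr@start[i] + pr@width[i], mlen[i])
        if (tail_validates(tail_seq, member_seqs[-i], mat)) {
          new_rep <- substr(paste0(new_rep, tail_seq), 1, max_len)
          break
        }
      }
    }
    left_tail <- pr@start - 1
    cand_l <- which(ok & sc >= 30 & sr_all@start <= 3 & left_tail >= min_tail)
    if (length(cand_l) && nchar(new_rep) < max_len) {
      for (i in cand_l[order(-sc[cand_l])]) {
        head_seq <- substr(member_seqs[i], 1, pr@start[i] - 1)
        if (tail_validates(head_seq, member_seqs[-i], mat)) {
          room <- max_len - nchar(new_rep)
          if (nchar(head_seq) > room) {
            head_seq <- substr(head_seq, nchar(head_seq) - room + 1, nchar(head_seq))
          }
          new_rep <- paste0(head_seq, new_rep)
          break
        }
      }
    }
    stable <- new_rep == rep_seq
    rep_seq <- new_rep
    if (stable) break
  }
  rep_seq
}

## A candidate extension tail is accepted when it aligns to at least one
## other cluster member at >= 50% of its length in score (i.e. well above
## the score a background tail reaches against unrelated reads).
tail_validates <- function(tail_seq, others, mat, n_check = 12) {
  len <- nchar(tail_seq)
  if (len < 4) return(FALSE)
  if (!length(others)) return(TRUE)
  if (length(others) > n_check) {
    others <- others[round(seq(1, length(others), length.out = n_check))]
  }
  sc <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(others), Biostrings::DNAString(tail_seq),
    type = "local", substitutionMatrix = mat, gapOpening = 5, gapExtension = 2,
    scoreOnly = TRUE)
  max(sc) >= max(12, 0.5 * len)
}

#' Call tandem periodicity by self-shift identity
#'
#' For each shift `s` in `[min_period, L/2]` the sequence is compared,
#' ungapped, with itself shifted by `s`; `f(s)` is the fraction of matching
#' positions.  The sequence is called tandem when `max f(s) >= threshold`
#' and the reported period is the smallest local maximum of `f` reaching the
#' threshold (so that multiples of the true period are avoided).  Periods
#' below `min_period` surface as multiples; lower `min_period` to resolve
#' them.
#'
#' @param representative DNA string (a cluster representative).
#' @param min_period Smallest shift examined (default 4).
#' @param threshold Match-fraction threshold for tandem calls (default 0.7).
#' @return A one-row tibble: `tandem` (logical), `period` (bp, `NA` when not
#'   tandem), `max_identity`, `evaluable` (FALSE when the sequence is too
#'   short to test).
#' @export
detect_tandem <- function(representative, min_period = 4, threshold = 0.7) {
  L <- nchar(representative)
  if (L < 2 * min_period) {
    return(tibble(tandem = FALSE, period = NA_integer_,
                  max_identity = NA_real_, evaluable = FALSE))
  }
  x <- utf8ToInt(representative)
  smax <- floor(L / 2)
  shifts <- min_period:smax
  f <- vapply(shifts, function(s) {
    mean(x[1:(L - s)] == x[(s + 1):L])
  }, numeric(1))
  tandem <- max(f) >= threshold
  period <- NA_integer_
  if (tandem) {
    nf <- length(f)
    is_local_max <- f >= c(-Inf, f[-nf]) & f >= c(f[-1], -Inf)
    qual <- which(is_local_max & f >= threshold)
    period <- shifts[qual[1]]
  }
  tibble(tandem = tandem, period = as.integer(period),
         max_identity = max(f), evaluable = TRUE)
}

#' Discover tandem repeat clusters in a read sample
#'
#' Convenience wrapper tying the discovery stage together: build the k-mer
#' graph, cluster, build a polished representative per retained cluster and
#' call tandemness.
#'
#' @param reads Sampled read tibble.
#' @param k,min_shared Graph parameters, see [build_kmer_graph()].
#' @param min_proportion Cluster floor, see [cluster_reads()].
#' @param min_period,threshold Tandem-call parameters, see [detect_tandem()].
#' @param method Clustering method, see [cluster_reads()].
#' @param polish_min_reads Polished, extended representatives are built only
#'   for clusters with at least this many reads; smaller clusters are judged
#'   on the seed insert alone (for short monomers the mate-joined seed
#'   already spans two periods, and the many tiny read-overlap chains of
#'   background sequence would otherwise dominate the runtime).
#' @return The [cluster_reads()] tibble extended with `member_units`
#'   (mate-joined inserts), `representative`, `tandem`, `period`,
#'   `max_identity`.
#' @export
discover_clusters <- function(reads, k = 13, min_shared = 3,
                              min_proportion = 1e-5, min_period = 4,
                              threshold = 0.7, polish_min_reads = 5,
                              method = c("components", "louvain")) {
  method <- match.arg(method)
  g <- build_kmer_graph(reads, k = k, min_shared = min_shared)
  cl <- cluster_reads(g, min_proportion = min_proportion, reads = reads,
                      method = method)
  units <- unit_lookup(reads)
  res <- purrr::map_dfr(seq_len(nrow(cl)), function(i) {
    # the seed is the insert of a high-degree member's pair (contiguous
    # mate-joined sequence), and polishing/extension work on insert units,
    # so representatives can grow to ~insert + period.  Several candidate
    # seeds are tried: in a community that mixes a small tandem family with
    # background read chains the single top-degree read can be background.
    member_units <- cluster_units(cl$members[[i]], reads, units)
    seed_seq <- NULL
    td <- NULL
    for (cand in cl$seed_candidates[[i]]) {
      cseq <- unname(join_mate_pair(cand, reads))
      ctd <- detect_tandem(cseq, min_period, threshold)
      if (is.null(seed_seq)) { seed_seq <- cseq; td <- ctd }
      if (isTRUE(ctd$tandem)) { seed_seq <- cseq; td <- ctd; break }
    }
    rep_seq <- seed_seq
    if (cl$n_reads[i] >= polish_min_reads) {
      rep_seq <- cluster_representative(member_units, seed_seq = seed_seq)
      td2 <- detect_tandem(rep_seq, min_period, threshold)
      # keep the polished call unless polishing lost a clean seed-level call
      if (isTRUE(td2$tandem) || !isTRUE(td$tandem)) {
        td <- td2
      } else {
        rep_seq <- seed_seq
      }
    }
    tibble(member_units = list(member_units), representative = rep_seq,
           tandem = td$tandem, period = td$period,
           max_identity = td$max_identity)
  })
  out <- bind_rows(cbind(cl, res))
  attr(out, "dropped_bp") <- attr(cl, "dropped_bp")
  attr(out, "total_bp") <- attr(cl, "total_bp")
  out
}
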
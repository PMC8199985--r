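# Shared fixtures and independent oracles used across the suite.

# Plain dynamic-programming Levenshtein distance, independent of the
# implementation's adist-based path.
dp_edit_distance <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (x[i] != y[j]))
    }
  }
  d[n + 1, m + 1]
}

# Union of all minimum spanning trees by exhaustive enumeration of labeled
# trees (Prufer sequences); tractable for n <= 6.
brute_force_msn <- function(D) {
  n <- nrow(D)
  if (n == 1) return(matrix(numeric(0), 0, 2))
  if (n == 2) return(matrix(c(1, 2), 1, 2))
  prufer_to_tree <- function(pr) {
    degree <- rep(1L, n)
    for (v in pr) degree[v] <- degree[v] + 1L
    edges <- matrix(0L, n - 1, 2)
    ptr <- 1
    avail <- degree
    for (v in pr) {
      leaf <- which(avail == 1L)[1]
      edges[ptr, ] <- c(leaf, v); ptr <- ptr + 1
      avail[leaf] <- 0L
      avail[v] <- avail[v] - 1L
    }
    last <- which(avail >= 1L)
    edges[ptr, ] <- last
    edges
  }
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  min_trees <- list()
  for (r in seq_len(nrow(seqs))) {
    tr <- prufer_to_tree(as.integer(seqs[r, ]))
    w <- sum(D[tr])
    if (w < best - 1e-9) { best <- w; min_trees <- list(tr) }
    else if (abs(w - best) <= 1e-9) min_trees <- c(min_trees, list(tr))
  }
  edges <- unique(do.call(rbind, lapply(min_trees, function(tr) {
    t(apply(tr, 1, sort))
  })))
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

# Independent greedy overlap resolution mirroring the documented rule,
# written as a direct loop over interval vectors.
greedy_resolve_oracle <- function(start, end, score, max_overlap = 10) {
  ord <- order(-score, start)
  kept_s <- integer(0); kept_e <- integer(0); kept_idx <- integer(0)
  for (i in ord) {
    s <- start[i]; e <- end[i]
    ov <- pmax(0, pmin(e, kept_e) - pmax(s, kept_s))
    if (length(ov) && any(ov >= max_overlap)) next
    for (j in seq_along(kept_s)) {
      if (s < kept_s[j] && e > kept_s[j]) e <- kept_s[j]
      else if (s < kept_e[j] && e > kept_e[j]) s <- kept_e[j]
      else if (s >= kept_s[j] && e <= kept_e[j]) { s <- e <- 0L; break }
    }
    if (e - s <= 0) next
    kept_s <- c(kept_s, s); kept_e <- c(kept_e, e); kept_idx <- c(kept_idx, i)
  }
  data.frame(idx = kept_idx, start = kept_s, end = kept_e)
}

# Small simulated satellitome shared by discovery/consensus tests.
tiny_satellitome <- function(seed = 42) {
  specs <- dplyr::bind_rows(
    sat_family_spec("famA", make_consensus(120, 0.7, 101), 0.025, 0.05),
    sat_family_spec("famB", make_consensus(60, 0.6, 102), 0.008, 0.03))
  g <- build_genome(specs, 4e5, seed = seed)
  reads <- sim_reads(g, coverage = 1, error_rate = 0.001,
                     seed = seed + 1)
  list(genome = g, reads = reads, specs = specs)
}
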
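# Inter-family similarity screening and minimum spanning networks of
# subfamilies.  Similarity significance uses an empirical shuffled-sequence
# null with a Gumbel tail fit (local alignment scores of shuffled sequences
# follow an extreme-value distribution), standing in for BLAST's E-value at
# the same nominal threshold (expectation 0.001).

#' All-vs-all similarity screen of consensus sequences
#'
#' Every pair is aligned locally (rotation-aware: the shorter sequence is
#' doubled; both strands tried).  Significance is assessed against a null of
#' `n_shuffles` column-shuffled versions of the shorter sequence: a Gumbel
#' distribution is fitted to the null scores by moments and the upper-tail
#' probability of the observed score is reported.  Pairs with
#' `p <= max_p` are returned.
#'
#' @param consensuses Tibble with `name` and `consensus` columns, or a named
#'   character vector.
#' @param max_p Significance threshold (default 0.001).
#' @param n_shuffles Shuffles per pair for the null (default 200).
#' @param seed Integer seed for the shuffles.
#' @return Tibble `family_a`, `family_b`, `aln_length`, `identity_pct`,
#'   `score`, `p_value` — one row per significant (unordered) pair.
#' @export
pairwise_similarity <- function(consensuses, max_p = 0.001, n_shuffles = 200,
                                seed = 1) {
  cons <- as_consensus_tbl(consensuses)
  n <- nrow(cons)
  if (n < 2) abort("Need at least 2 consensus sequences.")
  with_seed(seed, {
    out <- list()
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        a <- cons$consensus[i]; b <- cons$consensus[j]
        obs <- aligned_similarity(a, b)
        shorter <- if (nchar(a) <= nchar(b)) a else b
        longer <- if (nchar(a) <= nchar(b)) b else a
        null_scores <- vapply(seq_len(n_shuffles), function(s) {
          shuf <- paste(sample(strsplit(shorter, "")[[1]]), collapse = "")
          aligned_similarity(shuf, longer)$score
        }, numeric(1))
        p <- gumbel_upper_p(obs$score, null_scores)
        if (p <= max_p) {
          out[[length(out) + 1]] <- tibble(
            family_a = cons$name[i], family_b = cons$name[j],
            aln_length = obs$aln_length,
            identity_pct = 100 * obs$identity,
            score = obs$score, p_value = p)
        }
      }
    }
    if (length(out)) bind_rows(out) else
      tibble(family_a = character(), family_b = character(),
             aln_length = integer(), identity_pct = double(),
             score = double(), p_value = double())
  })
}

as_consensus_tbl <- function(x) {
  if (is.character(x)) {
    nm <- names(x) %||% paste0("seq", seq_along(x))
    return(tibble(name = nm, consensus = unname(x)))
  }
  if (is.data.frame(x) && all(c("name", "consensus") %in% names(x))) {
    return(as_tibble(x))
  }
  abort("Expected a named character vector or a name/consensus tibble.")
}

## Upper-tail p of `x` under a Gumbel fitted by moments to `null`.
gumbel_upper_p <- function(x, null) {
  m <- mean(null); s <- sd(null)
  if (!is.finite(s) || s == 0) return(as.numeric(x <= m))
  beta <- s * sqrt(6) / pi
  mu <- m - 0.5772156649 * beta
  1 - exp(-exp(-(x - mu) / beta))
}

#' Rotation-minimized edit distances between subfamily consensuses
#'
#' Pairwise Levenshtein distances, each minimized over all circular rotations
#' of one sequence (tandem monomers have no natural origin).  Warns when two
#' members differ more than 3-fold in length.
#'
#' @param consensuses Named character vector or `name`/`consensus` tibble.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
pairwise_distance <- function(consensuses) {
  cons <- as_consensus_tbl(consensuses)
  n <- nrow(cons)
  if (n < 2) abort("Need at least 2 subfamily consensuses.")
  lens <- nchar(cons$consensus)
  if (max(lens) / min(lens) > 3) {
    warn("Some consensuses differ more than 3-fold in length; distances may be dominated by indels.")
  }
  D <- matrix(0, n, n, dimnames = list(cons$name, cons$name))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- rotation_distance(cons$consensus[i], cons$consensus[j])
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Build an epsilon = 0 minimum spanning network
#'
#' The union of all minimum spanning trees of the distance matrix: distinct
#' distances are visited in ascending order, and every edge at the current
#' distance whose endpoints are not yet connected by strictly smaller
#' distances is added.  Edge labels are the distances ("mutational steps");
#' node weights are the supplied abundances.
#'
#' @param D Symmetric distance matrix with zero diagonal (dimnames used as
#'   node names).
#' @param abundances Optional named vector of node weights (e.g. genome
#'   proportions).
#' @param lengths Optional named vector of monomer lengths for plotting.
#' @return A `satkit_msn` object: list with `nodes` (tibble `name`, `weight`,
#'   `length`), `edges` (tibble `from`, `to`, `steps`) and `graph` (igraph).
#' @export
build_msn <- function(D, abundances = NULL, lengths = NULL) {
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-9))) {
    abort("Distance matrix must be symmetric.")
  }
  if (any(!is.finite(D))) abort("Distance matrix must be finite.")
  n <- nrow(D)
  nms <- rownames(D) %||% paste0("node", seq_len(n))
  edges <- tibble(from = integer(), to = integer(), steps = double())
  if (n > 1) {
    pairs <- which(upper.tri(D), arr.ind = TRUE)
    pd <- tibble(i = pairs[, 1], j = pairs[, 2], d = D[pairs])
    comp <- seq_len(n)  # union-find over strictly-smaller-distance edges
    find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
    for (dv in sort(unique(pd$d))) {
      batch <- pd[pd$d == dv, , drop = FALSE]
      add <- purrr::pmap_lgl(batch, function(i, j, d) find(i) != find(j))
      if (any(add)) {
        edges <- bind_rows(edges, tibble(from = batch$i[add], to = batch$j[add],
                                         steps = batch$d[add]))
      }
      # union only after the whole distance class is processed (tie retention)
      for (r in which(add)) {
        ri <- find(batch$i[r]); rj <- find(batch$j[r])
        if (ri != rj) comp[ri] <- rj
      }
    }
  }
  nodes <- tibble(
    name = nms,
    weight = if (is.null(abundances)) rep(1, n) else unname(abundances[nms]),
    length = if (is.null(lengths)) NA_real_ else unname(lengths[nms]))
  g <- igraph::graph_from_data_frame(
    tibble(from = nms[edges$from], to = nms[edges$to], steps = edges$steps),
    directed = FALSE, vertices = nodes)
  structure(list(nodes = nodes,
                 edges = tibble(from = nms[edges$from], to = nms[edges$to],
                                steps = edges$steps),
                 graph = g),
            class = "satkit_msn")
}

#' @export
print.satkit_msn <- function(x, ...) {
  cat(sprintf("<satkit_msn> %d node(s), %d edge(s), total steps %s\n",
              nrow(x$nodes), nrow(x$edges),
              format(sum(x$edges$steps))))
  invisible(x)
}

#' Write a minimum spanning network to GraphML
#'
#' @param msn A `satkit_msn`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msn_graphml <- function(msn, path) {
  igraph::write_graph(msn$graph, path, format = "graphml")
  invisible(path)
}
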
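#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join distinct n row_number desc across pull rename count
#' @importFrom stats median sd cor setNames rbinom runif rmultinom pt
#' @importFrom utils head adist
#' @importFrom methods as
NULL

DNA_BASES <- c("A", "C", "G", "T")

## Evaluate `expr` under a fixed RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

## Derive a reproducible child seed below 2^31 from a root seed and an index.
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(i)) %% 2147483629L)
}

random_dna <- function(n, at_content = 0.5) {
  p <- c(at_content / 2, (1 - at_content) / 2, (1 - at_content) / 2, at_content / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T).
#' @return Character vector of the same length with each sequence
#'   reverse-complemented.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAAC"))
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

at_fraction <- function(x) {
  n <- nchar(x)
  at <- nchar(gsub("[CG]", "", x))
  at / n
}

## Rotate a sequence right by `r` positions (r in 0..nchar-1): the last r
## characters move to the front.
rotate_seq <- function(x, r) {
  n <- nchar(x)
  r <- r %% n
  if (r == 0) return(x)
  paste0(substr(x, n - r + 1, n), substr(x, 1, n - r))
}

# ---- integer k-mer codes -----------------------------------------------------

## Canonical k-mer codes for a set of reads.  Bases are encoded A=0 C=1 G=2 T=3
## and a k-mer becomes the base-4 integer of its bases; the canonical code is
## min(code, code of reverse complement).  Exact in doubles for k <= 25.
## Returns a tibble (read = read index, kmer = canonical code), deduplicated.
canonical_kmers <- function(seqs, k) {
  stopifnot(k >= 4, k <= 25)
  lens <- nchar(seqs)
  keep <- lens >= k
  if (!any(keep)) return(tibble(read = integer(), kmer = double()))
  idx <- which(keep)
  cat_seq <- paste(seqs[keep], collapse = "")
  b <- utf8ToInt(cat_seq)
  code <- integer(length(b))
  code[b == 65L] <- 0L; code[b == 67L] <- 1L
  code[b == 71L] <- 2L; code[b == 84L] <- 3L
  n <- length(code)
  npos <- n - k + 1
  fwd <- numeric(npos)
  rev <- numeric(npos)
  for (i in seq_len(k)) {
    sl <- code[i:(i + npos - 1)]
    fwd <- fwd + sl * 4^(k - i)
    rev <- rev + (3 - sl) * 4^(i - 1)
  }
  canon <- pmin(fwd, rev)
  # map positions back to reads; drop windows spanning two reads
  ends <- cumsum(lens[keep])
  starts <- c(1, head(ends, -1) + 1)
  read_of <- rep.int(seq_along(idx), lens[keep])
  pos_read <- read_of[seq_len(npos)]
  ok <- seq_len(npos) + k - 1 <= ends[pos_read]
  out <- tibble(read = idx[pos_read[ok]], kmer = canon[ok])
  dplyr::distinct(out)
}

# ---- FASTA / FASTQ -----------------------------------------------------------

#' Read sequences into a tibble
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] returning a tibble
#' with `id` and `seq` columns, the container used throughout satkit.
#'
#' @param path Path to a FASTA (or FASTQ for `read_fastq_tbl`) file.
#' @return A tibble with columns `id` (character) and `seq` (character).
#' @export
read_fasta_tbl <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(id = sub("\\s.*$", "", names(x)), seq = as.character(x))
}

#' @rdname read_fasta_tbl
#' @export
read_fastq_tbl <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(id = sub("\\s.*$", "", names(x)), seq = as.character(x))
}

#' Write a sequence tibble to FASTA or FASTQ
#'
#' @param tbl Tibble with `id` and `seq` columns.
#' @param path Output path.
#' @param width Line width for FASTA wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta_tbl <- function(tbl, path, width = 60) {
  x <- Biostrings::DNAStringSet(setNames(tbl$seq, tbl$id))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' @rdname write_fasta_tbl
#' @export
write_fastq_tbl <- function(tbl, path) {
  x <- Biostrings::DNAStringSet(setNames(tbl$seq, tbl$id))
  qual <- Biostrings::BStringSet(strrep("I", nchar(tbl$seq)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

## Write a tibble as TSV/CSV with provenance comment lines ("# key: value").
write_tsv_provenance <- function(tbl, path, provenance = NULL, sep = "\t") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(provenance)) {
    writeLines(sprintf("# %s: %s", nm, provenance[[nm]]), con)
  }
  utils::write.table(tbl, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_comments <- function(path) {
  as_tibble(utils::read.delim(path, comment.char = "#", sep = "\t",
                              stringsAsFactors = FALSE, check.names = FALSE))
}
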
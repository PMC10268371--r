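#' RNA secondary structure as an arc diagram
#'
#' An `rna_structure` stores a secondary structure as its arc diagram: `n`
#' nucleotides on a backbone (1-based positions) and a set of base pairs
#' `(i, j)` with `i < j`, each pair drawn as an arc above the backbone.
#' Pseudoknots appear as crossing arcs.
#'
#' Invariants enforced by the constructor:
#' * every position belongs to at most one pair;
#' * arcs join non-consecutive positions (`j >= i + 2`);
#' * all positions lie in `[1, length]`.
#'
#' @param length Positive integer, number of nucleotides.
#' @param pairs Two-column integer matrix (or empty) of base pairs; rows may
#'   be given in either order, they are normalised to `i < j` and sorted.
#' @param sequence Optional nucleotide string over `A,C,G,U,N` of length
#'   `length`. Characters outside that alphabet are mapped to `N`.
#' @return An object of class `rna_structure` with elements `length`,
#'   `pairs` (sorted two-column matrix) and `sequence` (string or `NULL`).
#' @examples
#' rna_structure(6, rbind(c(1, 6), c(2, 5)))
#' @export
rna_structure <- function(length, pairs = NULL, sequence = NULL) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L)
    stop("'length' must be a positive integer")
  if (is.null(pairs) || NROW(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2L)
  } else {
    pairs <- matrix(as.integer(as.matrix(pairs)), ncol = 2L)
    swap <- pairs[, 1L] > pairs[, 2L]
    pairs[swap, ] <- pairs[swap, c(2L, 1L)]
    pairs <- unique(pairs)
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  }
  if (NROW(pairs)) {
    if (any(!is.finite(pairs)) || any(pairs < 1L) || any(pairs > length))
      stop("pair indices must lie in [1, length]")
    if (any(pairs[, 2L] - pairs[, 1L] < 2L))
      stop("arcs must join non-consecutive positions (j >= i + 2)")
    idx <- as.vector(pairs)
    if (anyDuplicated(idx))
      stop("a position appears in more than one pair")
  }
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence)[1L])
    if (nchar(sequence) != length)
      stop("'sequence' length does not match 'length'")
    sequence <- gsub("[^ACGUN]", "N", sequence)
  }
  structure(
    list(length = length, pairs = pairs, sequence = sequence),
    class = "rna_structure"
  )
}

#' @export
print.rna_structure <- function(x, ...) {
  cr <- crossing_pairs(x)
  cat(sprintf(
    "RNA secondary structure: %d nt, %d base pairs, %d crossing arc pair%s (%s)\n",
    x$length, nrow(x$pairs), nrow(cr), if (nrow(cr) == 1L) "" else "s",
    if (nrow(cr)) "pseudoknotted" else "pseudoknot-free"
  ))
  if (!is.null(x$sequence)) cat(" sequence: ", x$sequence, "\n", sep = "")
  invisible(x)
}

#' @export
format.rna_structure <- function(x, ...) {
  sprintf("<rna_structure: %d nt, %d pairs>", x$length, nrow(x$pairs))
}

is_rna_structure <- function(x) inherits(x, "rna_structure")

#' Crossing arc pairs of a structure
#'
#' Two arcs `(i, j)` and `(k, l)` with `i < k` cross iff `i < k < j < l`.
#' A structure is pseudoknot-free exactly when no two of its arcs cross.
#'
#' @param x An [rna_structure].
#' @return An integer matrix with columns `i1, j1, i2, j2`, one row per
#'   unordered pair of crossing arcs, with `(i1, j1)` the arc that opens
#'   first; zero rows for a pseudoknot-free structure.
#' @examples
#' crossing_pairs(parse_dotbracket("([)]"))
#' @export
crossing_pairs <- function(x) {
  stopifnot(is_rna_structure(x))
  p <- x$pairs
  k <- nrow(p)
  out <- matrix(integer(0), ncol = 4L,
                dimnames = list(NULL, c("i1", "j1", "i2", "j2")))
  if (k < 2L) return(out)
  # pairs are sorted by opening position, so row a opens before row b > a
  res <- vector("list", k - 1L)
  for (a in seq_len(k - 1L)) {
    b <- (a + 1L):k
    hit <- p[b, 1L] < p[a, 2L] & p[b, 2L] > p[a, 2L]
    if (any(hit)) {
      bb <- b[hit]
      res[[a]] <- cbind(p[rep(a, length(bb)), , drop = FALSE],
                        p[bb, , drop = FALSE])
    }
  }
  res <- do.call(rbind, res)
  if (!is.null(res) && nrow(res)) {
    out <- res
    colnames(out) <- c("i1", "j1", "i2", "j2")
  }
  out
}
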
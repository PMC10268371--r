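#' Build the dual graph of a secondary structure
#'
#' In the dual-graph representation every stem is a vertex and every single
#' strand of more than one unpaired nucleotide that connects structural
#' elements is an edge between the two stems flanking it (a self-loop when
#' both flanks belong to the same stem, as in a hairpin loop). The 5' and
#' 3' dangling ends have no representation. Multi-edges are kept: the graph
#' is a multigraph.
#'
#' A stem is a maximal helix: regions (stacked runs of pairs) separated by
#' bulges or internal loops of at most `merge_gap` unpaired nucleotides per
#' strand are merged into a single vertex, consistent with the "more than
#' one unpaired nucleotide" edge threshold. Single-pair stems are admitted.
#'
#' @param x An [rna_structure] with at least one pair.
#' @param merge_gap Maximal per-strand unpaired gap inside one stem
#'   (default 1).
#' @return A list of class `dual_graph` with `n_vertices`, `edges` (a
#'   two-column matrix, one row per edge, self-loops as equal entries) and
#'   `stems` (list of pair matrices per vertex).
#' @examples
#' g <- build_dual_graph(parse_dotbracket("((...))..((...))"))
#' g$n_vertices  # 2
#' @export
build_dual_graph <- function(x, merge_gap = 1L) {
  stopifnot(is_rna_structure(x))
  regions <- extract_regions(x)
  if (!length(regions)) stop("structure has no stems")
  m <- length(regions)
  # merge directly nested regions separated by <= merge_gap nt per strand
  stem_id <- seq_len(m)
  if (m >= 2L) {
    outer_i <- vapply(regions, function(r) r[1L, 1L], integer(1))
    outer_j <- vapply(regions, function(r) r[1L, 2L], integer(1))
    inner_i <- vapply(regions, function(r) r[nrow(r), 1L], integer(1))
    inner_j <- vapply(regions, function(r) r[nrow(r), 2L], integer(1))
    paired <- logical(x$length)
    paired[as.vector(x$pairs)] <- TRUE
    gap_free <- function(from, to) {     # open interval (from, to) unpaired
      from + 1L > to - 1L || !any(paired[(from + 1L):(to - 1L)])
    }
    for (a in seq_len(m)) {
      for (b in seq_len(m)) {
        if (a == b) next
        # b directly nested inside a's innermost pair, tiny gaps both sides?
        g5 <- outer_i[b] - inner_i[a] - 1L
        g3 <- inner_j[a] - outer_j[b] - 1L
        if (g5 >= 0L && g3 >= 0L && g5 <= merge_gap && g3 <= merge_gap &&
            gap_free(inner_i[a], outer_i[b]) &&
            gap_free(outer_j[b], inner_j[a])) {
          old <- stem_id[b]
          stem_id[stem_id == old] <- stem_id[a]
        }
      }
    }
  }
  stem_id <- match(stem_id, sort(unique(stem_id)))
  n_stems <- max(stem_id)
  stems <- lapply(seq_len(n_stems), function(s) {
    do.call(rbind, regions[stem_id == s])
  })
  # vertex of every paired position
  pos_stem <- integer(x$length)
  for (s in seq_len(n_stems)) pos_stem[as.vector(stems[[s]])] <- s
  # unpaired runs of > 1 nt between paired positions become edges
  unpaired <- pos_stem == 0L
  edges <- NULL
  r <- rle(unpaired)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k] || r$lengths[k] <= 1L) next
    u1 <- starts[k]; u2 <- ends[k]
    if (u1 == 1L || u2 == x$length) next        # dangling 5'/3' end
    edges <- rbind(edges, c(pos_stem[u1 - 1L], pos_stem[u2 + 1L]))
  }
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2L)
  swap <- edges[, 1L] > edges[, 2L]
  edges[swap, ] <- edges[swap, c(2L, 1L)]
  structure(list(n_vertices = n_stems, edges = edges, stems = stems),
            class = "dual_graph")
}

#' @export
print.dual_graph <- function(x, ...) {
  nl <- sum(x$edges[, 1L] == x$edges[, 2L])
  cat(sprintf("dual graph: %d stem vertices, %d edges (%d self-loop%s)\n",
              x$n_vertices, nrow(x$edges), nl, if (nl == 1L) "" else "s"))
  invisible(x)
}

#' Construct a dual graph directly from an edge list
#'
#' Mostly useful for spectral experiments on hand-built multigraphs;
#' [build_dual_graph()] is the route from a structure.
#'
#' @param n_vertices Number of vertices.
#' @param edges Two-column matrix of vertex pairs; equal entries are
#'   self-loops. May have zero rows.
#' @return A `dual_graph`.
#' @export
dual_graph <- function(n_vertices, edges = matrix(integer(0), ncol = 2L)) {
  edges <- matrix(as.integer(as.matrix(edges)), ncol = 2L)
  n_vertices <- as.integer(n_vertices)
  stopifnot(n_vertices >= 1L,
            !nrow(edges) || (min(edges) >= 1L && max(edges) <= n_vertices))
  structure(list(n_vertices = n_vertices, edges = edges, stems = NULL),
            class = "dual_graph")
}

#' Laplacian matrix of a dual graph
#'
#' `L = D - A` with `A[i, j]` the number of edges between `i` and `j`,
#' `A[i, i] = 2` per self-loop on `i`, and `D` diagonal with the number of
#' edge endpoints at each vertex (a self-loop contributes 2). With these
#' conventions every row of `L` sums to zero, `L` is positive semidefinite
#' and its smallest eigenvalue is 0 with the constant eigenvector.
#'
#' @param g A `dual_graph` (from [build_dual_graph()]).
#' @return A symmetric numeric matrix.
#' @export
graph_laplacian <- function(g) {
  stopifnot(inherits(g, "dual_graph"))
  n <- g$n_vertices
  A <- matrix(0, n, n)
  for (e in seq_len(nrow(g$edges))) {
    i <- g$edges[e, 1L]; j <- g$edges[e, 2L]
    if (i == j) A[i, i] <- A[i, i] + 2
    else {
      A[i, j] <- A[i, j] + 1
      A[j, i] <- A[j, i] + 1
    }
  }
  D <- diag(rowSums(A), n)
  D - A
}

dual_graph_connected <- function(g) {
  n <- g$n_vertices
  if (n <= 1L) return(TRUE)
  seen <- logical(n)
  seen[1L] <- TRUE
  queue <- 1L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- unique(c(g$edges[g$edges[, 1L] == v, 2L],
                   g$edges[g$edges[, 2L] == v, 1L]))
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Fiedler-vector features of a dual graph
#'
#' Spectral summary of the graph topology used by the RAG-2D comparison:
#' (1) take the unit-norm eigenvector of the second-smallest Laplacian
#' eigenvalue (the Fiedler value, positive iff the graph is connected);
#' (2) sort its components ascending into `v`; (3) scale them to
#' `v_i * (n - 1) / (v_n - v_1)`; (4) regress the scaled components on
#' their rank `1..n` by least squares. The slope `s` and the mean squared
#' residual `e` are the features.
#'
#' The eigenvector sign is fixed so that the sorted vector is
#' lexicographically smallest (first component most negative). Graphs with
#' fewer than 2 vertices get the degenerate sentinel `(0, 0)`.
#'
#' @param g A `dual_graph`.
#' @return A list of class `fiedler_features` with `s`, `e`,
#'   `fiedler_value`, and the intermediate `scaled` components.
#' @examples
#' g <- build_dual_graph(parse_dotbracket("((...))..((...))"))
#' fiedler_features(g)[c("s", "e")]
#' @export
fiedler_features <- function(g) {
  stopifnot(inherits(g, "dual_graph"))
  n <- g$n_vertices
  if (n < 2L) {
    return(structure(list(s = 0, e = 0, fiedler_value = NA_real_,
                          scaled = numeric(0)),
                     class = "fiedler_features"))
  }
  if (!dual_graph_connected(g))
    stop("dual graph is disconnected: the Fiedler value is 0")
  L <- graph_laplacian(g)
  eig <- eigen(L, symmetric = TRUE)
  lambda2 <- eig$values[n - 1L]          # values come in decreasing order
  mu2 <- eig$vectors[, n - 1L]
  mu2 <- mu2 / sqrt(sum(mu2^2))
  v <- sort(mu2)
  vneg <- sort(-mu2)
  # sign convention: lexicographically smallest sorted vector
  for (k in seq_len(n)) {
    if (vneg[k] < v[k] - 1e-12) { v <- vneg; break }
    if (v[k] < vneg[k] - 1e-12) break
  }
  scaled <- v * (n - 1) / (v[n] - v[1L])
  fit <- stats::lm.fit(cbind(1, seq_len(n)), scaled)
  s <- unname(fit$coefficients[2L])
  e <- mean(fit$residuals^2)
  structure(list(s = s, e = e, fiedler_value = lambda2, scaled = scaled),
            class = "fiedler_features")
}

#' @export
print.fiedler_features <- function(x, ...) {
  cat(sprintf("Fiedler features: s = %.4f, e = %.4f (lambda2 = %.4f)\n",
              x$s, x$e, x$fiedler_value))
  invisible(x)
}

#' Euclidean distance between two feature pairs
#'
#' @param f1,f2 `fiedler_features` objects, or numeric vectors `c(s, e)`.
#' @return `sqrt((s1 - s2)^2 + (e1 - e2)^2)`.
#' @export
rag2d_distance <- function(f1, f2) {
  p1 <- if (inherits(f1, "fiedler_features")) c(f1$s, f1$e) else as.numeric(f1)
  p2 <- if (inherits(f2, "fiedler_features")) c(f2$s, f2$e) else as.numeric(f2)
  sqrt(sum((p1[1:2] - p2[1:2])^2))
}
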
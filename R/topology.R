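#' Extract regions (maximal helix stacks) of a structure
#'
#' A region is a maximal run of consecutively nested pairs
#' `(i, j), (i+1, j-1), ...` with no unpaired nucleotide inside the run --
#' a stack of helices with no bulges or internal loops. Regions are the
#' unit over which the pseudoknot order is defined.
#'
#' @param x An [rna_structure].
#' @return A list of regions, each a two-column matrix of its pairs ordered
#'   from the outermost pair inwards. Every pair of `x` belongs to exactly
#'   one region; regions are ordered by their outermost opening position.
#' @examples
#' length(extract_regions(parse_dotbracket("((.((..))))")))  # 2
#' @export
extract_regions <- function(x) {
  stopifnot(is_rna_structure(x))
  p <- x$pairs
  if (!nrow(p)) return(list())
  key <- paste(p[, 1L], p[, 2L])
  has <- function(i, j) paste(i, j) %in% key
  starts <- which(!has(p[, 1L] - 1L, p[, 2L] + 1L))
  lapply(starts, function(s) {
    i <- p[s, 1L]; j <- p[s, 2L]
    run <- NULL
    while (has(i, j)) {
      run <- rbind(run, c(i, j))
      i <- i + 1L
      j <- j - 1L
    }
    colnames(run) <- c("i", "j")
    run
  })
}

# do two regions (pair matrices) contain any crossing pair of arcs?
regions_cross <- function(a, b) {
  for (r in seq_len(nrow(a))) {
    i <- a[r, 1L]; j <- a[r, 2L]
    if (any((i < b[, 1L] & b[, 1L] < j & j < b[, 2L]) |
            (b[, 1L] < i & i < b[, 2L] & b[, 2L] < j)))
      return(TRUE)
  }
  FALSE
}

# region conflict graph: adjacency matrix over regions, edge = crossing
region_conflict_graph <- function(regions) {
  m <- length(regions)
  adj <- matrix(FALSE, m, m)
  if (m >= 2L) {
    for (a in seq_len(m - 1L)) {
      for (b in (a + 1L):m) {
        if (regions_cross(regions[[a]], regions[[b]]))
          adj[a, b] <- adj[b, a] <- TRUE
      }
    }
  }
  adj
}

#' Genus of an RNA secondary structure
#'
#' The genus is the minimum number of handles that must be attached to a
#' sphere so that the arc diagram can be drawn without arc crossings, all
#' arcs on the same side of the backbone. It is computed exactly by the
#' fatgraph boundary walk: the backbone is collapsed to a single fatgraph
#' vertex whose cyclic order is the backbone order of the `2n` arc
#' endpoints; the boundary components of the thickened diagram are the
#' cycles of the permutation `sigma o tau`, where `sigma` is the cyclic
#' endpoint order and `tau` swaps the two endpoints of each arc. With `n`
#' arcs and `r` boundary loops, `2g = n - r + 1`.
#'
#' A pseudoknot-free diagram has genus 0; the minimal crossing diagram
#' `{(1,3),(2,4)}` has genus 1; the genus of structures laid side by side
#' on disjoint intervals is the sum of their genera.
#'
#' @param x An [rna_structure].
#' @return A list of class `genus_result` with elements `n_arcs`,
#'   `boundary_loops`, `genus` and `boundary_cycles` (the traced cycles
#'   over endpoint slots, for auditing the walk).
#' @examples
#' genus(rna_structure(4, rbind(c(1, 3), c(2, 4))))$genus  # 1
#' @export
genus <- function(x) {
  stopifnot(is_rna_structure(x))
  p <- x$pairs
  n <- nrow(p)
  if (n == 0L) {
    return(structure(list(n_arcs = 0L, boundary_loops = 1L, genus = 0L,
                          boundary_cycles = list()),
                     class = "genus_result"))
  }
  ends <- sort(as.vector(p))          # 2n endpoint slots in backbone order
  slot <- seq_along(ends)
  tau <- integer(2L * n)              # endpoint involution along each arc
  for (a in seq_len(n)) {
    s1 <- match(p[a, 1L], ends)
    s2 <- match(p[a, 2L], ends)
    tau[s1] <- s2
    tau[s2] <- s1
  }
  sigma <- c(slot[-1L], slot[1L])     # next endpoint around the backbone
  perm <- sigma[tau]                  # boundary walk: cross the arc, step on
  seen <- logical(2L * n)
  cycles <- list()
  for (s in slot) {
    if (seen[s]) next
    cyc <- integer(0)
    cur <- s
    while (!seen[cur]) {
      seen[cur] <- TRUE
      cyc <- c(cyc, cur)
      cur <- perm[cur]
    }
    cycles[[length(cycles) + 1L]] <- cyc
  }
  r <- length(cycles)
  g <- (n - r + 1L) / 2
  stopifnot(g == floor(g), g >= 0)
  structure(list(n_arcs = n, boundary_loops = r, genus = as.integer(g),
                 boundary_cycles = cycles),
            class = "genus_result")
}

#' @export
print.genus_result <- function(x, ...) {
  cat(sprintf("genus %d (n = %d arcs, r = %d boundary loops)\n",
              x$genus, x$n_arcs, x$boundary_loops))
  invisible(x)
}

# exact maximum independent set of an adjacency matrix restricted to `verts`,
# returned as the lexicographically smallest maximum-cardinality vertex set.
# Branch and bound over include/exclude of the smallest remaining vertex.
max_independent_set <- function(adj, verts = seq_len(nrow(adj))) {
  mis_size <- function(vs) {
    if (!length(vs)) return(0L)
    v <- vs[1L]
    rest <- vs[-1L]
    take <- 1L + mis_size(rest[!adj[v, rest]])
    skip <- mis_size(rest)
    max(take, skip)
  }
  target <- mis_size(verts)
  chosen <- integer(0)
  avail <- verts
  while (length(chosen) < target) {
    for (v in avail) {
      rest <- avail[avail > v & !adj[v, avail]]
      if (1L + mis_size(rest) + length(chosen) >= target) {
        chosen <- c(chosen, v)
        avail <- rest
        break
      }
    }
  }
  chosen
}

# greedy maximal independent set: repeatedly take the minimum-degree vertex
# (ties: smallest index), drop its neighbours
greedy_independent_set <- function(adj, verts = seq_len(nrow(adj))) {
  chosen <- integer(0)
  avail <- verts
  while (length(avail)) {
    deg <- colSums(adj[avail, avail, drop = FALSE])
    v <- avail[which.min(deg)]       # which.min takes the first minimum
    chosen <- c(chosen, v)
    avail <- avail[avail != v & !adj[v, avail]]
  }
  sort(chosen)
}

#' Pseudoknot order of a structure
#'
#' Regions are layered into crossing-free sets: layer 0 is a
#' maximum-cardinality subset of regions with no crossings among them,
#' layer 1 a maximum crossing-free subset of the remainder, and so on.
#' Each region's order is its layer index and the structure's pseudoknot
#' order is the index of the deepest layer. A pseudoknot-free structure
#' has order 0; two mutually crossing regions give order 1; three pairwise
#' crossing regions give order 2.
#'
#' @param x An [rna_structure].
#' @param exact If `TRUE` (default) each layer is an exact maximum
#'   independent set of the region conflict graph, found by exhaustive
#'   branch-and-bound (ties broken towards the lexicographically smallest
#'   set of region indices, regions ordered by opening position).
#'   If `FALSE`, a greedy minimum-degree heuristic is used.
#' @param max_exact_regions Exact mode refuses structures with more regions
#'   than this cap (default 20) -- switch to `exact = FALSE` beyond it.
#' @return A list of class `pseudoknot_order` with `region_orders` (integer
#'   per region, in [extract_regions] order), `structure_order`, and
#'   `regions`.
#' @examples
#' pseudoknot_order(parse_dotbracket("((..[[..))..]]"))$structure_order  # 1
#' @export
pseudoknot_order <- function(x, exact = TRUE, max_exact_regions = 20L) {
  stopifnot(is_rna_structure(x))
  regions <- extract_regions(x)
  m <- length(regions)
  if (m == 0L) {
    return(structure(list(region_orders = integer(0), structure_order = 0L,
                          regions = regions),
                     class = "pseudoknot_order"))
  }
  if (exact && m > max_exact_regions)
    stop("exact mode refused: ", m, " regions exceed the cap of ",
         max_exact_regions, " (use exact = FALSE)")
  adj <- region_conflict_graph(regions)
  orders <- rep(NA_integer_, m)
  remaining <- seq_len(m)
  layer <- 0L
  while (length(remaining)) {
    set <- if (exact) max_independent_set(adj, remaining)
           else greedy_independent_set(adj, remaining)
    orders[set] <- layer
    remaining <- setdiff(remaining, set)
    layer <- layer + 1L
  }
  structure(list(region_orders = orders,
                 structure_order = max(orders),
                 regions = regions),
            class = "pseudoknot_order")
}

#' @export
print.pseudoknot_order <- function(x, ...) {
  cat(sprintf("pseudoknot order %d (%d region%s)\n", x$structure_order,
              length(x$regions), if (length(x$regions) == 1L) "" else "s"))
  invisible(x)
}

#' Genus and pseudoknot-order dissimilarities
#'
#' Both invariants induce a trivial dissimilarity between two structures:
#' the absolute difference of their genera (`genus_distance`) or of their
#' pseudoknot orders (`order_distance`). Structures with equal invariant
#' are at distance 0, so clustering on these matrices essentially recovers
#' the equivalence classes of the invariant.
#'
#' @param a,b [rna_structure] objects.
#' @param ... Passed on to [pseudoknot_order()] (e.g. `exact`).
#' @return A single non-negative number.
#' @export
genus_distance <- function(a, b) {
  abs(genus(a)$genus - genus(b)$genus)
}

#' @rdname genus_distance
#' @export
order_distance <- function(a, b, ...) {
  abs(pseudoknot_order(a, ...)$structure_order -
      pseudoknot_order(b, ...)$structure_order)
}
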
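# Shared fixtures and independent oracles used across the suite.

# random valid structure by rejection: k arcs over n positions, every arc
# spanning >= 2, endpoints disjoint; independent of the package generators
random_structure <- function(n, k, seed) {
  set.seed(seed)
  pairs <- NULL
  used <- logical(n)
  tries <- 0L
  while (NROW(pairs) < k && tries < 500L) {
    tries <- tries + 1L
    ij <- sort(sample(which(!used), 2L))
    if (ij[2] - ij[1] < 2L) next
    pairs <- rbind(pairs, ij)
    used[ij] <- TRUE
  }
  rna_structure(n, pairs)
}

# O(n^2) brute-force enumeration of crossing arc pairs
oracle_crossings <- function(x) {
  p <- x$pairs
  out <- NULL
  k <- nrow(p)
  if (k >= 2L) {
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        i <- p[a, 1]; j <- p[a, 2]; kk <- p[b, 1]; l <- p[b, 2]
        if (i < kk && kk < j && j < l) out <- rbind(out, c(i, j, kk, l))
      }
    }
  }
  if (is.null(out)) out <- matrix(integer(0), ncol = 4L)
  out
}

# --- ASPRA alignment oracle: exhaustive head-based recursion over all
# ordered-forest alignments (first-tree case analysis with every split of
# the opposite forest); exponential, for tiny trees only.
tree_children <- function(t) {
  if (is.null(t$left)) list() else list(t$left, t$right)
}

oracle_align_forests <- function(F1, F2, sc) {
  if (!length(F1) && !length(F2)) return(0)
  best <- Inf
  if (length(F1)) {
    t1 <- F1[[1]]; R1 <- F1[-1]; C1 <- tree_children(t1)
    for (split in 0:length(F2)) {
      P <- F2[seq_len(split)]
      S <- if (split < length(F2)) F2[(split + 1L):length(F2)] else list()
      cand <- sc$delete(t1$label) +
        oracle_align_forests(C1, P, sc) + oracle_align_forests(R1, S, sc)
      best <- min(best, cand)
    }
  }
  if (length(F2)) {
    t2 <- F2[[1]]; R2 <- F2[-1]; C2 <- tree_children(t2)
    for (split in 0:length(F1)) {
      P <- F1[seq_len(split)]
      S <- if (split < length(F1)) F1[(split + 1L):length(F1)] else list()
      cand <- sc$insert(t2$label) +
        oracle_align_forests(P, C2, sc) + oracle_align_forests(S, R2, sc)
      best <- min(best, cand)
    }
  }
  if (length(F1) && length(F2)) {
    t1 <- F1[[1]]; t2 <- F2[[1]]
    cand <- sc$replace(t1$label, t2$label) +
      oracle_align_forests(tree_children(t1), tree_children(t2), sc) +
      oracle_align_forests(F1[-1], F2[-1], sc)
    best <- min(best, cand)
  }
  best
}

oracle_align_trees <- function(t1, t2, sc = aspra_scoring()) {
  F1 <- if (identical(t1$label, "EMPTY")) list() else list(t1)
  F2 <- if (identical(t2$label, "EMPTY")) list() else list(t2)
  oracle_align_forests(F1, F2, sc)
}

# --- exhaustive layering oracle over region conflict graphs: bitmask
# enumeration of all independent subsets (<= 15 regions), peeling the
# lexicographically smallest maximum independent set each round (the same
# documented tie-break as the implementation, found by a different search)
oracle_layer_count <- function(adj) {
  m <- nrow(adj)
  if (m == 0L) return(0L)
  is_independent <- function(vs) {
    length(vs) < 2L || !any(adj[vs, vs])
  }
  lex_less <- function(a, b) {
    for (k in seq_len(min(length(a), length(b)))) {
      if (a[k] < b[k]) return(TRUE)
      if (a[k] > b[k]) return(FALSE)
    }
    length(a) < length(b)
  }
  layers <- 0L
  remaining <- seq_len(m)
  while (length(remaining)) {
    best <- integer(0)
    nr <- length(remaining)
    for (mask in seq_len(2^nr) - 1L) {
      vs <- remaining[bitwAnd(mask, 2^(seq_len(nr) - 1L)) > 0L]
      if (!is_independent(vs)) next
      if (length(vs) > length(best) ||
          (length(vs) == length(best) && lex_less(vs, best)))
        best <- vs
    }
    remaining <- setdiff(remaining, best)
    layers <- layers + 1L
  }
  layers
}

oracle_pseudoknot_order <- function(x) {
  regions <- extract_regions(x)
  adj <- pktaxa:::region_conflict_graph(regions)
  max(oracle_layer_count(adj) - 1L, 0L)
}

# two partitions equal as set partitions?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}
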
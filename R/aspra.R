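#' Build the structural RNA tree of a structure
#'
#' A structural RNA tree abstracts an arc diagram into a binary operator
#' tree over three relations between arcs: concatenation (one structure
#' followed by another), nesting (one inside an arc) and crossing (a
#' pseudoknot). The construction repeatedly selects the arc with the
#' rightmost paired nucleotide and classifies its relation to the remaining
#' arcs: crossing if it crosses any of them (the node is annotated with the
#' number of arcs crossed), otherwise nesting if the selected arc's interval
#' contains the span of the remainder, otherwise concatenation. The left
#' child is the tree of the remaining structure, the right child the leaf
#' for the selected arc; recursion stops when a single arc remains. The
#' primary sequence plays no role.
#'
#' @param x An [rna_structure] with at least one pair.
#' @return A nested-list tree of class `structural_rna_tree`. Each node is a
#'   list with `label` (`"LEAF"`, `"CONCAT"`, `"NEST"` or `"CROSS(k)"` where
#'   `k` is the crossing count), plus `left`/`right` for internal nodes and
#'   `arc` for leaves. Structures with zero pairs yield the empty-tree
#'   sentinel `empty_structural_tree()`.
#' @examples
#' build_structural_tree(parse_dotbracket("([)]"))$label  # "CROSS(1)"
#' @export
build_structural_tree <- function(x) {
  stopifnot(is_rna_structure(x))
  p <- x$pairs
  if (nrow(p) == 0L) return(empty_structural_tree())
  build_tree_rec(p)
}

build_tree_rec <- function(p) {
  if (nrow(p) == 1L) {
    return(structure(list(label = "LEAF", arc = as.integer(p[1L, ])),
                     class = "structural_rna_tree"))
  }
  sel <- which.max(p[, 2L])           # rightmost paired nucleotide is unique
  arc <- p[sel, ]
  rest <- p[-sel, , drop = FALSE]
  ncross <- sum((rest[, 1L] < arc[1L] & arc[1L] < rest[, 2L] &
                 rest[, 2L] < arc[2L]) |
                (arc[1L] < rest[, 1L] & rest[, 1L] < arc[2L] &
                 arc[2L] < rest[, 2L]))
  label <- if (ncross > 0L) {
    sprintf("CROSS(%d)", ncross)
  } else if (arc[1L] < min(rest[, 1L])) {
    # selected arc encloses the whole remainder (its right end is maximal)
    "NEST"
  } else {
    "CONCAT"
  }
  structure(list(label = label,
                 left = build_tree_rec(rest),
                 right = structure(list(label = "LEAF",
                                        arc = as.integer(arc)),
                                   class = "structural_rna_tree")),
            class = "structural_rna_tree")
}

#' @rdname build_structural_tree
#' @export
empty_structural_tree <- function() {
  structure(list(label = "EMPTY"), class = "structural_rna_tree")
}

is_empty_tree <- function(t) identical(t$label, "EMPTY")

tree_size <- function(t) {
  if (is_empty_tree(t)) return(0L)
  if (t$label == "LEAF") return(1L)
  1L + tree_size(t$left) + tree_size(t$right)
}

#' @export
print.structural_rna_tree <- function(x, ...) {
  show <- function(t, indent) {
    lab <- if (t$label == "LEAF")
      sprintf("LEAF (%d,%d)", t$arc[1L], t$arc[2L]) else t$label
    cat(strrep("  ", indent), lab, "\n", sep = "")
    if (!is.null(t$left)) {
      show(t$left, indent + 1L)
      show(t$right, indent + 1L)
    }
  }
  show(x, 0L)
  invisible(x)
}

#' Edit-cost scheme for structural tree alignment
#'
#' The alignment score charges a cost per node of the alignment tree:
#' `replace(x, y)` for a node matching labels `x` and `y`, `insert(y)` /
#' `delete(x)` for nodes aligned against a gap. The default is the unit
#' scheme: replacement costs 0 for equal labels (crossing nodes with
#' different crossing counts count as different) and 1 otherwise; insertion
#' and deletion cost 1. Replacement must be symmetric with zero diagonal
#' for the distance to be symmetric and vanish on identical trees.
#'
#' @param replace Function of two label strings returning a cost.
#' @param insert,delete Functions of one label string returning a cost.
#' @return A list of class `aspra_scoring`.
#' @export
aspra_scoring <- function(replace = function(x, y) as.numeric(x != y),
                          insert = function(x) 1,
                          delete = function(x) 1) {
  structure(list(replace = replace, insert = insert, delete = delete),
            class = "aspra_scoring")
}

# flatten a structural tree to parallel arrays for the alignment DP
flatten_tree <- function(t) {
  labels <- character(0)
  children <- list()
  add <- function(node) {
    id <- length(labels) + 1L
    labels[id] <<- node$label
    children[[id]] <<- integer(0)
    if (!is.null(node$left)) {
      l <- add(node$left)
      r <- add(node$right)
      children[[id]] <<- c(l, r)
    }
    id
  }
  if (is_empty_tree(t)) {
    return(list(labels = character(0), children = list(), root = 0L))
  }
  root <- add(t)
  list(labels = labels, children = children, root = root)
}

#' Align two structural RNA trees
#'
#' Computes the minimum-cost ordered tree alignment of two structural RNA
#' trees under a scoring scheme, by dynamic programming over ordered-forest
#' alignments (the classical tree-alignment recurrences over sub-forest
#' spans). The result is the ASPRA distance of the underlying structures.
#'
#' @param t1,t2 `structural_rna_tree` objects (the empty sentinel allowed).
#' @param scoring An [aspra_scoring] scheme.
#' @return The minimal alignment cost, a single non-negative number.
#' @export
align_trees <- function(t1, t2, scoring = aspra_scoring()) {
  stopifnot(inherits(t1, "structural_rna_tree"),
            inherits(t2, "structural_rna_tree"),
            inherits(scoring, "aspra_scoring"))
  f1 <- flatten_tree(t1)
  f2 <- flatten_tree(t2)
  if (f1$root == 0L && f2$root == 0L) return(0)
  rep_cost <- scoring$replace
  ins_cost <- scoring$insert
  del_cost <- scoring$delete

  # whole-subtree gap costs
  sub_gap <- function(f, costf) {
    n <- length(f$labels)
    out <- numeric(n)
    for (id in rev(seq_len(n)))   # children always have larger preorder ids
      out[id] <- costf(f$labels[id]) + sum(out[f$children[[id]]])
    out
  }
  del_all <- sub_gap(f1, del_cost)
  ins_all <- sub_gap(f2, ins_cost)
  if (f1$root == 0L) return(ins_all[f2$root])
  if (f2$root == 0L) return(del_all[f1$root])

  memoT <- new.env(parent = emptyenv())
  memoF <- new.env(parent = emptyenv())

  # forest distance: children p..q of node i (tree 1) vs k..l of j (tree 2);
  # i or j = 0 denotes the root-level forest holding the whole tree
  dF <- function(i, p, q, j, k, l) {
    c1 <- if (i == 0L) f1$root else f1$children[[i]]
    c2 <- if (j == 0L) f2$root else f2$children[[j]]
    s1 <- if (p > q) integer(0) else c1[p:q]
    s2 <- if (k > l) integer(0) else c2[k:l]
    if (!length(s1) && !length(s2)) return(0)
    if (!length(s1)) return(sum(ins_all[s2]))
    if (!length(s2)) return(sum(del_all[s1]))
    keyv <- paste(i, p, q, j, k, l, sep = ",")
    hit <- memoF[[keyv]]
    if (!is.null(hit)) return(hit)
    ci <- c1[q]
    cj <- c2[l]
    best <- min(
      dF(i, p, q - 1L, j, k, l) + del_all[ci],
      dF(i, p, q, j, k, l - 1L) + ins_all[cj],
      dF(i, p, q - 1L, j, k, l - 1L) + dT(ci, cj)
    )
    # align cj against an inserted node whose children take the suffix p..q
    nc_j <- length(f2$children[[cj]])
    for (m in p:q) {
      cand <- ins_cost(f2$labels[cj]) +
        dF(i, p, m - 1L, j, k, l - 1L) +
        dF(i, m, q, cj, 1L, nc_j)
      if (cand < best) best <- cand
    }
    nc_i <- length(f1$children[[ci]])
    for (m in k:l) {
      cand <- del_cost(f1$labels[ci]) +
        dF(i, p, q - 1L, j, k, m - 1L) +
        dF(ci, 1L, nc_i, j, m, l)
      if (cand < best) best <- cand
    }
    memoF[[keyv]] <- best
    best
  }

  dT <- function(i, j) {
    keyv <- paste(i, j, sep = ",")
    hit <- memoT[[keyv]]
    if (!is.null(hit)) return(hit)
    ch1 <- f1$children[[i]]
    ch2 <- f2$children[[j]]
    best <- rep_cost(f1$labels[i], f2$labels[j]) +
      dF(i, 1L, length(ch1), j, 1L, length(ch2))
    # root of one tree aligned inside a branch of the other
    for (r in ch2) {
      cand <- ins_all[j] - ins_all[r] + dT(i, r)
      if (cand < best) best <- cand
    }
    for (r in ch1) {
      cand <- del_all[i] - del_all[r] + dT(r, j)
      if (cand < best) best <- cand
    }
    memoT[[keyv]] <- best
    best
  }

  dT(f1$root, f2$root)
}

#' ASPRA distance between two structures
#'
#' Builds the structural RNA tree of each structure and returns the
#' minimum-cost ordered tree alignment under the scoring scheme. With the
#' default (symmetric, unit-cost) scheme this is a symmetric dissimilarity
#' that is 0 exactly on structures with identical structural trees.
#'
#' @param a,b [rna_structure] objects.
#' @param scoring An [aspra_scoring] scheme.
#' @return A single non-negative number.
#' @examples
#' a <- parse_dotbracket("((...))")
#' b <- parse_dotbracket("(...)(...)")
#' aspra_distance(a, b)
#' @export
aspra_distance <- function(a, b, scoring = aspra_scoring()) {
  align_trees(build_structural_tree(a), build_structural_tree(b), scoring)
}
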
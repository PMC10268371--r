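test_that("regions are maximal stacks covering every pair exactly once", {
  r1 <- extract_regions(parse_dotbracket("((..))"))
  expect_length(r1, 1L)
  expect_equal(nrow(r1[[1]]), 2L)

  r2 <- extract_regions(parse_dotbracket("((.((..))))"))
  expect_length(r2, 2L)
  expect_equal(sort(vapply(r2, nrow, integer(1))), c(2L, 2L))

  for (seed in 1:15) {
    s <- random_structure(n = 40, k = 8, seed = seed)
    regions <- extract_regions(s)
    all_pairs <- do.call(rbind, regions)
    # union of regions = pairs, each pair exactly once
    expect_equal(all_pairs[order(all_pairs[, 1]), , drop = FALSE],
                 unname(s$pairs), ignore_attr = TRUE)
    # maximality: no region extends by a stacked neighbour pair
    key <- paste(s$pairs[, 1], s$pairs[, 2])
    for (r in regions) {
      expect_false(paste(r[1, 1] - 1L, r[1, 2] + 1L) %in% key)
      m <- nrow(r)
      expect_false(paste(r[m, 1] + 1L, r[m, 2] - 1L) %in% key)
    }
  }
})

test_that("genus matches hand-traced boundary walks", {
  expect_equal(genus(rna_structure(4, rbind(c(1, 3), c(2, 4))))$genus, 1L)
  expect_equal(genus(parse_dotbracket("((..))"))$genus, 0L)
  expect_equal(genus(parse_dotbracket("..."))$genus, 0L)
  g <- genus(rna_structure(4, rbind(c(1, 3), c(2, 4))))
  expect_equal(g$n_arcs, 2L)
  expect_equal(g$boundary_loops, 1L)
})

test_that("genus is zero exactly on pseudoknot-free structures", {
  for (seed in 1:40) {
    s <- random_structure(n = 30, k = 7, seed = seed)
    g <- genus(s)
    expect_equal(g$genus == 0L, nrow(crossing_pairs(s)) == 0L)
    expect_gte(g$genus, 0L)
  }
})

test_that("the boundary walk consumes every ribbon side exactly once", {
  for (seed in 1:15) {
    s <- random_structure(n = 30, k = 7, seed = seed)
    g <- genus(s)
    slots <- sort(unlist(g$boundary_cycles))
    expect_equal(slots, seq_len(2L * g$n_arcs))
  }
})

test_that("genus adds up over concatenation on disjoint intervals", {
  shift_concat <- function(a, b) {
    rna_structure(a$length + b$length,
                  rbind(a$pairs, b$pairs + a$length))
  }
  for (seed in 1:15) {
    a <- random_structure(n = 24, k = 6, seed = seed)
    b <- random_structure(n = 24, k = 6, seed = seed + 1000L)
    expect_equal(genus(shift_concat(a, b))$genus,
                 genus(a)$genus + genus(b)$genus)
  }
})

test_that("stacking an arc into a helix does not change the genus", {
  thicken <- function(s) {
    # double the outermost pair of each region where there is room
    p <- s$pairs
    extra <- NULL
    for (r in extract_regions(s)) {
      i <- r[1, 1] - 1L; j <- r[1, 2] + 1L
      used <- c(as.vector(p), as.vector(extra))
      if (i >= 1L && j <= s$length && !(i %in% used) && !(j %in% used))
        extra <- rbind(extra, c(i, j))
    }
    rna_structure(s$length, rbind(p, extra))
  }
  for (seed in 1:10) {
    s <- random_structure(n = 40, k = 6, seed = seed)
    expect_equal(genus(thicken(s))$genus, genus(s)$genus)
  }
})

test_that("pseudoknot order anchors: nested 0, two crossing 1, clique 2", {
  expect_equal(pseudoknot_order(parse_dotbracket("((.((..))))"))$structure_order, 0L)
  two <- rna_structure(15, rbind(c(1, 10), c(2, 9), c(5, 15), c(6, 14)))
  expect_equal(pseudoknot_order(two, exact = TRUE)$structure_order, 1L)
  three <- parse_dotbracket("AA.BB.CC.aa.bb.cc")
  expect_equal(pseudoknot_order(three, exact = TRUE)$structure_order, 2L)
  expect_equal(oracle_pseudoknot_order(three), 2L)
})

test_that("order layers are crossing-free and adjacent layers conflict", {
  for (seed in 1:12) {
    s <- gen_pseudoknotted_structure(
      generator_config(seed = seed, crossing_count = 2L), pattern = "clique")
    po <- pseudoknot_order(s)
    adj <- pktaxa:::region_conflict_graph(po$regions)
    for (m in unique(po$region_orders)) {
      layer <- which(po$region_orders == m)
      expect_false(any(adj[layer, layer]))
      if (m > 0L) {
        below <- which(po$region_orders == m - 1L)
        for (v in layer) expect_true(any(adj[v, below]))
      }
    }
  }
})

test_that("order is zero iff the region conflict graph has no edges", {
  for (seed in 1:20) {
    s <- random_structure(n = 30, k = 6, seed = seed)
    adj <- pktaxa:::region_conflict_graph(extract_regions(s))
    expect_equal(pseudoknot_order(s)$structure_order == 0L, !any(adj))
  }
})

test_that("exact layering matches the exhaustive oracle; greedy bounds it", {
  for (seed in 1:40) {
    s <- random_structure(n = 36, k = 8, seed = seed)
    if (length(extract_regions(s)) > 10L) next
    exact <- pseudoknot_order(s, exact = TRUE)
    expect_equal(exact$structure_order, oracle_pseudoknot_order(s))
    # greedy yields a valid layering: never fewer layers than exact, each
    # layer crossing-free
    greedy <- pseudoknot_order(s, exact = FALSE)
    expect_gte(greedy$structure_order, exact$structure_order)
    adj <- pktaxa:::region_conflict_graph(greedy$regions)
    for (m in unique(greedy$region_orders)) {
      layer <- which(greedy$region_orders == m)
      expect_false(any(adj[layer, layer]))
    }
  }
})

test_that("greedy and exact layering agree on generated structure families", {
  for (seed in 1:10) {
    nested <- gen_nested_structure(generator_config(seed = seed))
    expect_equal(pseudoknot_order(nested, exact = FALSE)$structure_order,
                 pseudoknot_order(nested, exact = TRUE)$structure_order)
    for (pat in c("interleaved", "clique")) {
      s <- gen_pseudoknotted_structure(
        generator_config(seed = seed, crossing_count = 2L), pattern = pat)
      expect_equal(pseudoknot_order(s, exact = FALSE)$structure_order,
                   pseudoknot_order(s, exact = TRUE)$structure_order)
    }
  }
})

test_that("exact mode refuses oversized region sets", {
  db <- paste(rep("(...)", 25), collapse = ".")
  s <- parse_dotbracket(db)
  expect_error(pseudoknot_order(s, max_exact_regions = 20), "exceed")
  expect_equal(pseudoknot_order(s, exact = FALSE)$structure_order, 0L)
})

test_that("exact maximum independent sets match the igraph oracle", {
  skip_if_not_installed("igraph")
  set.seed(99)
  for (rep in 1:15) {
    m <- sample(3:9, 1)
    adj <- matrix(FALSE, m, m)
    for (a in seq_len(m - 1)) for (b in (a + 1):m)
      adj[a, b] <- adj[b, a] <- stats::runif(1) < 0.4
    mis <- pktaxa:::max_independent_set(adj)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_length(mis, igraph::independence_number(g))
    expect_false(any(adj[mis, mis]))
  }
})

test_that("invariant dissimilarities are absolute differences", {
  nest <- parse_dotbracket("((..))")
  cross <- rna_structure(4, rbind(c(1, 3), c(2, 4)))
  expect_equal(genus_distance(nest, nest), 0)
  expect_equal(genus_distance(nest, cross), 1)
  expect_equal(genus_distance(cross, nest), 1)
  expect_equal(order_distance(nest, parse_dotbracket("(((...)))")), 0)
  expect_equal(order_distance(nest, cross), 1)
})
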
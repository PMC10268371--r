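#' Configuration for the synthetic generators
#'
#' Bundles the knobs of the seeded generators that make the whole pipeline
#' testable without external data: rRNA-like nested structures, structures
#' with a controlled number of crossing region pairs, and planted-partition
#' distance matrices with known taxon labels.
#'
#' Defaults emulate a small benchmark of rRNA-like molecules: a handful of
#' helices of 3-6 stacked pairs, hairpin loops of 3-6 nt, and clearly
#' separated taxa (within-taxon dissimilarities around 0.2, between-taxon
#' around 1.0).
#'
#' @param seed Integer seed; every generator is a pure function of
#'   (seed, its call-site tag), so adding generators does not shift the
#'   stream of existing ones.
#' @param n_molecules,n_taxa Size of a generated molecule set and number of
#'   planted taxa (`n_taxa <= n_molecules`).
#' @param helix_count,helix_length,loop_length Integer ranges `c(min, max)`
#'   for the number of helices per structure, stacked pairs per helix and
#'   unpaired nucleotides per loop/spacer.
#' @param crossing_count Target number of crossing region pairs for the
#'   pseudoknotted generator.
#' @param within_taxon_distance,between_taxon_distance Numeric `c(mean, sd)`
#'   of the dissimilarity draws inside and across planted blocks; a
#'   separated regime has between mean well above within mean.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_molecules = 30L,
                             n_taxa = 3L,
                             helix_count = c(3L, 6L),
                             helix_length = c(3L, 6L),
                             loop_length = c(3L, 6L),
                             crossing_count = 1L,
                             within_taxon_distance = c(mean = 0.2, sd = 0.05),
                             between_taxon_distance = c(mean = 1.0, sd = 0.1)) {
  stopifnot(n_taxa >= 1L, n_taxa <= n_molecules,
            all(helix_count >= 1L), all(helix_length >= 1L),
            all(loop_length >= 1L), crossing_count >= 0L,
            within_taxon_distance[1] >= 0, between_taxon_distance[1] >= 0)
  structure(list(seed = as.integer(seed),
                 n_molecules = as.integer(n_molecules),
                 n_taxa = as.integer(n_taxa),
                 helix_count = as.integer(helix_count),
                 helix_length = as.integer(helix_length),
                 loop_length = as.integer(loop_length),
                 crossing_count = as.integer(crossing_count),
                 within_taxon_distance = as.numeric(within_taxon_distance),
                 between_taxon_distance = as.numeric(between_taxon_distance)),
            class = "generator_config")
}

# deterministic sub-seed from (seed, tag); stays well below 2^31
mix_seed <- function(seed, tag) {
  h <- 0
  for (c in utf8ToInt(tag)) h <- (h * 31 + c) %% 2147483563
  as.integer((h + (as.numeric(seed) %% 2147483563) * 10007) %% 2147483563)
}

# evaluate expr under a local RNG stream; the caller's stream is untouched
with_local_seed <- function(seed, tag, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(mix_seed(seed, tag))
  expr
}

rint <- function(range) {
  if (range[1] >= range[length(range)]) return(range[1])
  sample(range[1]:range[length(range)], 1L)
}

#' Generate a pseudoknot-free, rRNA-like structure
#'
#' Draws a number of helices from `helix_count`, each with a stack depth
#' from `helix_length`, and assembles them by random nesting and
#' concatenation with unpaired loops/spacers from `loop_length`. The result
#' has no crossing arcs by construction (genus 0, pseudoknot order 0) and
#' is a pure function of `config$seed`.
#'
#' @param config A [generator_config()].
#' @return An [rna_structure].
#' @export
gen_nested_structure <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_local_seed(config$seed, "nested", {
    h <- rint(config$helix_count)
    db <- nested_db(h, config)
    parse_dotbracket(db)
  })
}

# random dot-bracket over k helices: first unit wraps a sub-structure,
# the rest is concatenated after a spacer
nested_db <- function(k, config) {
  dots <- function() strrep(".", rint(config$loop_length))
  if (k == 0L) return(dots())
  m <- rint(c(1L, k))
  len <- rint(config$helix_length)
  inner <- nested_db(m - 1L, config)
  if (m > 1L) inner <- paste0(dots(), inner, dots())  # keep helices distinct
  unit <- paste0(strrep("(", len), inner, strrep(")", len))
  rest <- if (k - m > 0L) paste0(dots(), nested_db(k - m, config)) else ""
  paste0(unit, rest)
}

#' Generate a structure with a controlled pseudoknot complexity
#'
#' Inserts helix pairs in the interleaved pattern `A..B..A'..B'` at
#' disjoint coordinate windows, which gives exact control of the region
#' conflict graph. With `pattern = "interleaved"` (default) the structure
#' contains `config$crossing_count` independent crossing region pairs
#' (pseudoknot order 1, genus equal to the count); with
#' `pattern = "clique"` it contains `config$crossing_count + 1` mutually
#' crossing regions (pseudoknot order `config$crossing_count`). A nested
#' tail drawn from the nested generator is concatenated so the structures
#' also exercise stem- and tree-based methods. A `crossing_count` of 0 is
#' routed to [gen_nested_structure()].
#'
#' @param config A [generator_config()].
#' @param pattern `"interleaved"` or `"clique"` (see above).
#' @return An [rna_structure].
#' @export
gen_pseudoknotted_structure <- function(config = generator_config(),
                                        pattern = c("interleaved", "clique")) {
  stopifnot(inherits(config, "generator_config"))
  pattern <- match.arg(pattern)
  if (config$crossing_count == 0L) return(gen_nested_structure(config))
  with_local_seed(config$seed, paste0("pseudoknotted-", pattern), {
    gap <- function() strrep(".", rint(config$loop_length))
    knot_db <- function(nreg) {
      # nreg mutually crossing regions: openings A B C ... then closings
      # a b c ... in the same order, every pair of regions crosses
      lens <- vapply(seq_len(nreg), function(i) rint(config$helix_length),
                     integer(1))
      open <- paste(vapply(seq_len(nreg), function(r)
        paste0(strrep(LETTERS[r], lens[r]), gap()), character(1)),
        collapse = "")
      close <- paste(vapply(seq_len(nreg), function(r)
        paste0(strrep(letters[r], lens[r]), gap()), character(1)),
        collapse = "")
      paste0(open, close)
    }
    db <- if (pattern == "interleaved") {
      paste(vapply(seq_len(config$crossing_count),
                   function(k) paste0(knot_db(2L), gap()), character(1)),
            collapse = "")
    } else {
      paste0(knot_db(config$crossing_count + 1L), gap())
    }
    db <- paste0(db, nested_db(rint(config$helix_count), config))
    parse_dotbracket(db)
  })
}

#' Generate a planted-partition distance matrix with taxon labels
#'
#' Molecules are split into `n_taxa` near-equal blocks. Within-block
#' dissimilarities are drawn from a normal around the within mean,
#' between-block ones around the between mean; negative draws are clamped
#' to 0 (the number of clamps is recorded in attribute `"n_clamped"`). The
#' matrix is symmetric with a zero diagonal.
#'
#' @param config A [generator_config()].
#' @return A list with `distances` (named symmetric matrix), `labels`
#'   (named character vector of planted taxa) and `ids`.
#' @export
gen_planted_partition <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_local_seed(config$seed, "planted-partition", {
    n <- config$n_molecules
    ids <- sprintf("M%03d", seq_len(n))
    taxa <- sprintf("taxon_%02d", sort(rep_len(seq_len(config$n_taxa), n)))
    names(taxa) <- ids
    D <- matrix(0, n, n, dimnames = list(ids, ids))
    wm <- config$within_taxon_distance
    bm <- config$between_taxon_distance
    n_clamped <- 0L
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        par <- if (taxa[i] == taxa[j]) wm else bm
        d <- stats::rnorm(1L, par[1], par[2])
        if (d < 0) {
          d <- 0
          n_clamped <- n_clamped + 1L
        }
        D[i, j] <- D[j, i] <- d
      }
    }
    attr(D, "n_clamped") <- n_clamped
    list(distances = D, labels = taxa, ids = ids)
  })
}

#' Generate a labelled set of structures
#'
#' One taxon per pseudoknot-complexity level: molecules of taxon `t` carry
#' `t - 1` crossing region pairs (taxon 1 is pseudoknot-free), so the
#' topological methods separate the taxa by construction while every
#' molecule still differs in its nested scaffold.
#'
#' @param config A [generator_config()].
#' @return A list with `structures` (named list of [rna_structure]) and
#'   `labels` (named character vector).
#' @export
gen_labeled_structures <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_molecules
  ids <- sprintf("M%03d", seq_len(n))
  taxa <- sprintf("taxon_%02d", sort(rep_len(seq_len(config$n_taxa), n)))
  names(taxa) <- ids
  structures <- vector("list", n)
  names(structures) <- ids
  for (k in seq_len(n)) {
    lvl <- as.integer(sub("taxon_", "", taxa[k]))
    sub <- config
    sub$seed <- mix_seed(config$seed, paste0("molecule-", k))
    sub$crossing_count <- lvl - 1L
    structures[[k]] <- if (lvl == 1L) gen_nested_structure(sub)
                       else gen_pseudoknotted_structure(sub)
  }
  list(structures = structures, labels = taxa)
}
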
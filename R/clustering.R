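check_distance_matrix <- function(D, tol = 1e-9) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("distance matrix must be square")
  if (any(!is.finite(D))) stop("distance matrix has non-finite entries")
  if (any(D < 0)) stop("distance matrix has negative entries")
  asym <- max(abs(D - t(D)))
  if (asym > tol)
    stop("distance matrix is not symmetric (max |D - t(D)| = ",
         format(asym), ")")
  D <- (D + t(D)) / 2
  diag(D) <- 0
  D
}

#' Agglomerative clustering of a dissimilarity matrix
#'
#' Bottom-up hierarchical clustering starting from singletons: at each step
#' the two closest clusters are merged and the inter-cluster dissimilarity
#' is updated according to the linkage -- the minimum over member pairs
#' (`single`), the maximum (`complete`) or the mean over all member pairs
#' (`average`). The dendrogram is cut to yield `k` clusters. Ward linkage
#' is deliberately not offered: it requires Euclidean distances, which
#' structure-comparison methods generally do not produce.
#'
#' @param D Symmetric, non-negative, zero-diagonal numeric matrix
#'   (asymmetries up to `1e-9` are averaged away). Row/column names are
#'   used as molecule IDs when present.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param linkage `"single"`, `"complete"` or `"average"`.
#' @return A list with `dendrogram` (an [stats::hclust] merge tree) and
#'   `partition` (named integer vector of cluster indices `1..k`).
#' @examples
#' pp <- gen_planted_partition(generator_config(seed = 7, n_molecules = 12))
#' cl <- agglomerative_cluster(pp$distances, k = 3, linkage = "average")
#' table(cl$partition, pp$labels)
#' @export
agglomerative_cluster <- function(D, k,
                                  linkage = c("single", "complete", "average")) {
  linkage <- match.arg(linkage)
  D <- check_distance_matrix(D)
  n <- nrow(D)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > n)
    stop("'k' must be between 1 and ", n)
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  part <- stats::cutree(hc, k = k)
  if (!is.null(rownames(D))) names(part) <- rownames(D)
  list(dendrogram = hc, partition = part)
}

#' Convert a similarity matrix to dissimilarities
#'
#' Similarities are min-max normalised into `[0, 1]` and flipped with
#' `diss = 1 - sim`; the diagonal is forced to 0. A constant matrix (zero
#' range) maps to all-zero dissimilarities with a warning.
#'
#' @param S Symmetric numeric matrix of similarities (finite entries).
#' @return A dissimilarity matrix of the same shape and dimnames.
#' @export
similarity_to_dissimilarity <- function(S) {
  if (!is.matrix(S) || nrow(S) != ncol(S))
    stop("similarity matrix must be square")
  if (any(!is.finite(S))) stop("similarity matrix has non-finite entries")
  if (max(abs(S - t(S))) > 1e-9) stop("similarity matrix is not symmetric")
  rng <- range(S)
  if (rng[1] == rng[2]) {
    warning("constant similarity matrix: all dissimilarities set to 0")
    D <- array(0, dim(S), dimnames = dimnames(S))
  } else {
    D <- 1 - (S - rng[1]) / (rng[2] - rng[1])
  }
  diag(D) <- 0
  D
}

#' Number of clusters implied by a label set
#'
#' The framework always asks agglomerative clustering for as many clusters
#' as there are distinct reference labels (e.g. taxa at the chosen
#' taxonomy rank).
#'
#' @param labels Non-empty vector of labels.
#' @return Integer count of distinct labels.
#' @export
num_clusters_from_labels <- function(labels) {
  if (!length(labels)) stop("empty label list")
  length(unique(as.character(labels)))
}
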
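check_label_pair <- function(true_labels, pred_labels, min_n = 1L) {
  t <- as.character(true_labels)
  p <- as.character(pred_labels)
  if (length(t) != length(p))
    stop("label vectors have different lengths (", length(t), " vs ",
         length(p), ")")
  if (length(t) < min_n)
    stop("need at least ", min_n, " samples")
  list(t = t, p = p)
}

#' Rand index of two partitions
#'
#' Pair-counting agreement between a reference partition `X` and a computed
#' partition `Y` of the same elements: with `a` the pairs placed together
#' in both, `b` the pairs separated in both, and `c`, `d` the discordant
#' pairs (together in exactly one of the two), the index is
#' `R = (a + b) / (a + b + c + d)`. The denominator equals `n(n-1)/2`. The
#' index lies in `[0, 1]`, is 1 iff the partitions coincide as set
#' partitions, and depends only on co-membership, never on label names.
#'
#' @param true_labels,pred_labels Equal-length label vectors (`n >= 2`).
#' @return A number in `[0, 1]`.
#' @examples
#' rand_index(c(0, 0, 1, 1), c(0, 1, 0, 1))  # 1/3
#' @export
rand_index <- function(true_labels, pred_labels) {
  lp <- check_label_pair(true_labels, pred_labels, min_n = 2L)
  n <- length(lp$t)
  same_t <- outer(lp$t, lp$t, "==")[upper.tri(diag(n))]
  same_p <- outer(lp$p, lp$p, "==")[upper.tri(diag(n))]
  a <- sum(same_t & same_p)
  b <- sum(!same_t & !same_p)
  c <- sum(same_t & !same_p)
  d <- sum(!same_t & same_p)
  (a + b) / (a + b + c + d)
}

# Shannon entropy terms with the 0 * log(0) := 0 convention
xlogx <- function(p, base) ifelse(p > 0, p * log(p, base = base), 0)

#' Homogeneity of a clustering against reference classes
#'
#' Entropy-based purity score `h = 1 - H(C|K) / H(C)`, where `H(C|K)` is
#' the conditional entropy of the reference classes given the clusters and
#' `H(C)` the class entropy. It is 1 when every cluster contains members of
#' a single class and, by convention, 1 when `H(C) = 0` (a single class).
#' The ratio is independent of the logarithm base.
#'
#' @param true_labels,pred_labels Equal-length label vectors.
#' @param base Logarithm base for the entropies (the score does not depend
#'   on it; exposed for auditing).
#' @return A number in `[0, 1]`.
#' @export
homogeneity <- function(true_labels, pred_labels, base = exp(1)) {
  lp <- check_label_pair(true_labels, pred_labels)
  n <- length(lp$t)
  n_c <- table(lp$t)
  H_C <- -sum(xlogx(n_c / n, base))
  if (H_C == 0) return(1)
  n_ck <- table(lp$t, lp$p)
  n_k <- colSums(n_ck)
  H_CK <- -sum(xlogx(sweep(n_ck, 2L, n_k, "/"), base) * rep(n_k, each = nrow(n_ck)) / n)
  1 - H_CK / H_C
}

#' Completeness of a clustering against reference classes
#'
#' Entropy-based togetherness score `c = 1 - H(K|C) / H(K)`, where `H(K|C)`
#' is the conditional entropy of the clusters given the reference classes
#' and `H(K)` the cluster entropy. It is 1 when all members of each class
#' land in one cluster and, by convention, 1 when `H(K) = 0` (a single
#' cluster). Completeness is the mirror image of homogeneity with the
#' roles of the two labelings exchanged.
#'
#' @inheritParams homogeneity
#' @return A number in `[0, 1]`.
#' @export
completeness <- function(true_labels, pred_labels, base = exp(1)) {
  lp <- check_label_pair(true_labels, pred_labels)
  n <- length(lp$t)
  n_k <- table(lp$p)
  H_K <- -sum(xlogx(n_k / n, base))
  if (H_K == 0) return(1)
  n_kc <- table(lp$p, lp$t)
  n_c <- colSums(n_kc)
  H_KC <- -sum(xlogx(sweep(n_kc, 2L, n_c, "/"), base) * rep(n_c, each = nrow(n_kc)) / n)
  1 - H_KC / H_K
}

#' All three clustering-evaluation metrics at once
#'
#' @inheritParams homogeneity
#' @return Named numeric vector `rand_index`, `homogeneity`,
#'   `completeness`, each in `[0, 1]` (1 = perfect agreement).
#' @export
metric_report <- function(true_labels, pred_labels) {
  c(rand_index = rand_index(true_labels, pred_labels),
    homogeneity = homogeneity(true_labels, pred_labels),
    completeness = completeness(true_labels, pred_labels))
}
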
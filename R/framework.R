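#' Pairwise dissimilarity matrix from structures
#'
#' Compares every pair of molecules with one of the four built-in methods:
#' `"genus"` and `"pskorder"` give the absolute difference of the
#' respective invariant, `"aspra"` the tree-alignment distance, `"rag2d"`
#' the Euclidean distance between the Fiedler features `(s, e)` of the dual
#' graphs. Input is either a folder of structure files (format detected by
#' extension, see [read_structure()]) or a named list of [rna_structure]
#' objects. A file that fails to parse aborts the run with its name, so
#' malformed molecules are excluded explicitly rather than silently.
#'
#' @param x Folder path or named list of [rna_structure] objects.
#' @param method One of `"genus"`, `"pskorder"`, `"aspra"`, `"rag2d"`.
#' @param scoring [aspra_scoring()] scheme for `method = "aspra"`.
#' @param exact Exact-mode flag for `method = "pskorder"` (see
#'   [pseudoknot_order()]).
#' @param headered Passed to the parsers when reading a folder.
#' @return Symmetric named matrix of dissimilarities with zero diagonal.
#' @export
compute_distance_matrix <- function(x,
                                    method = c("genus", "pskorder",
                                               "aspra", "rag2d"),
                                    scoring = aspra_scoring(),
                                    exact = TRUE,
                                    headered = TRUE) {
  method <- match.arg(method)
  structures <- load_structure_set(x, headered = headered)
  ids <- names(structures)
  n <- length(structures)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (method %in% c("genus", "pskorder")) {
    val <- vapply(structures, function(s) {
      if (method == "genus") as.numeric(genus(s)$genus)
      else as.numeric(pseudoknot_order(s, exact = exact)$structure_order)
    }, numeric(1))
    D <- abs(outer(val, val, "-"))
    dimnames(D) <- list(ids, ids)
  } else if (method == "rag2d") {
    feats <- compute_feature_table(structures)
    D <- as.matrix(stats::dist(feats[, c("s", "e")]))
    dimnames(D) <- list(ids, ids)
  } else {
    trees <- lapply(structures, build_structural_tree)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        D[i, j] <- D[j, i] <- align_trees(trees[[i]], trees[[j]], scoring)
      }
    }
  }
  diag(D) <- 0
  D
}

load_structure_set <- function(x, headered = TRUE) {
  if (is.character(x) && length(x) == 1L && dir.exists(x)) {
    files <- sort(list.files(x, pattern = "\\.(bpseq|ct|db|dbn|dot)$",
                             full.names = TRUE, ignore.case = TRUE))
    if (!length(files)) stop("no structure files found in ", x)
    structures <- lapply(files, function(f) {
      tryCatch(read_structure(f, headered = headered),
               error = function(e) stop("cannot parse '", basename(f),
                                        "': ", conditionMessage(e),
                                        call. = FALSE))
    })
    names(structures) <- tools::file_path_sans_ext(basename(files))
    if (anyDuplicated(names(structures)))
      stop("duplicate molecule IDs in ", x,
           " (same file stem in several formats?); ",
           "point at a single-format folder")
    structures
  } else if (is.list(x) && all(vapply(x, is_rna_structure, logical(1)))) {
    if (is.null(names(x)) || anyDuplicated(names(x)))
      stop("structure list must have unique names (molecule IDs)")
    x
  } else {
    stop("'x' must be a folder path or a named list of rna_structure objects")
  }
}

#' Per-molecule RAG-2D feature table
#'
#' The `(s, e)` Fiedler features of every molecule, the "pairs of features"
#' file of the pipeline; [features_to_distances()] turns it into a distance
#' matrix with [rag2d_distance()].
#'
#' @inheritParams compute_distance_matrix
#' @param features Data frame with columns `id`, `s`, `e`.
#' @return `compute_feature_table()`: data frame `id`, `s`, `e`;
#'   `features_to_distances()`: symmetric named distance matrix.
#' @export
compute_feature_table <- function(x, headered = TRUE) {
  structures <- load_structure_set(x, headered = headered)
  feats <- t(vapply(structures, function(s) {
    f <- fiedler_features(build_dual_graph(s))
    c(s = f$s, e = f$e)
  }, numeric(2)))
  data.frame(id = names(structures), s = feats[, "s"], e = feats[, "e"],
             row.names = names(structures))
}

#' @rdname compute_feature_table
#' @export
features_to_distances <- function(features) {
  stopifnot(is.data.frame(features), all(c("id", "s", "e") %in% names(features)))
  n <- nrow(features)
  D <- matrix(0, n, n, dimnames = list(features$id, features$id))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      D[i, j] <- rag2d_distance(c(features$s[i], features$e[i]),
                                c(features$s[j], features$e[j]))
    }
  }
  D
}

#' Cluster molecules and score the partition against reference labels
#'
#' The model-fitting core of the evaluation framework: given a pairwise
#' dissimilarity matrix and the reference labels (e.g. taxa at a chosen
#' taxonomy rank), agglomerative clustering is run for each requested
#' linkage with the number of clusters set to the number of distinct
#' labels, and the computed partition is scored with the rand index,
#' homogeneity and completeness.
#'
#' @param distances Symmetric named dissimilarity matrix; its IDs must
#'   match `names(labels)` one-to-one (order may differ).
#' @param labels Named character vector `id -> label`, or a data frame with
#'   an `id` column and a label column (see `rank`).
#' @param linkage Character vector, subset of
#'   `c("single", "complete", "average")`.
#' @param k Number of clusters; defaults to [num_clusters_from_labels()].
#' @param rank Label column used when `labels` is a data frame (default
#'   `"phylum"`, falling back to `"taxon"`).
#' @return An object of class `taxa_cluster`: a list with `metrics` (one
#'   row per linkage), `partitions`, `dendrograms`, `labels`, `k`.
#'   Methods: [print.taxa_cluster()], [summary.taxa_cluster()],
#'   [plot.taxa_cluster()].
#' @examples
#' pp <- gen_planted_partition(generator_config(seed = 3, n_molecules = 18))
#' fit <- taxa_cluster(pp$distances, pp$labels)
#' fit
#' @export
taxa_cluster <- function(distances, labels,
                         linkage = c("single", "complete", "average"),
                         k = NULL, rank = "phylum") {
  linkage <- match.arg(linkage, c("single", "complete", "average"),
                       several.ok = TRUE)
  labels <- as_label_vector(labels, rank = rank)
  ids <- rownames(distances)
  if (is.null(ids)) {
    if (nrow(distances) != length(labels))
      stop("unnamed distance matrix and labels differ in size")
    ids <- names(labels)
    dimnames(distances) <- list(ids, ids)
  }
  if (!setequal(ids, names(labels)) || length(ids) != length(labels))
    stop("molecule IDs of the distance matrix and the label set differ")
  labels <- labels[ids]
  if (is.null(k)) k <- num_clusters_from_labels(labels)
  fits <- lapply(linkage, function(l) agglomerative_cluster(distances, k, l))
  names(fits) <- linkage
  metrics <- do.call(rbind, lapply(linkage, function(l) {
    data.frame(linkage = l,
               t(metric_report(labels, fits[[l]]$partition)))
  }))
  rownames(metrics) <- NULL
  structure(list(metrics = metrics,
                 partitions = lapply(fits, `[[`, "partition"),
                 dendrograms = lapply(fits, `[[`, "dendrogram"),
                 labels = labels, k = k, n = length(labels)),
            class = "taxa_cluster")
}

as_label_vector <- function(labels, rank = "phylum") {
  if (is.data.frame(labels)) {
    if (!"id" %in% names(labels)) stop("label table needs an 'id' column")
    col <- if (rank %in% names(labels)) rank
           else if ("taxon" %in% names(labels)) "taxon"
           else stop("label table has neither a '", rank,
                     "' nor a 'taxon' column")
    out <- as.character(labels[[col]])
    names(out) <- as.character(labels$id)
    out
  } else {
    out <- as.character(labels)
    names(out) <- names(labels)
    if (is.null(names(out))) stop("labels must be named by molecule ID")
    out
  }
}

#' @export
print.taxa_cluster <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Agglomerative clustering of %d molecules into %d clusters\n", x$n, x$k))
  m <- x$metrics
  m[, -1L] <- round(m[, -1L], digits)
  print(m, row.names = FALSE)
  invisible(x)
}

#' @export
summary.taxa_cluster <- function(object, ...) {
  cat(sprintf("Reference labels: %d molecules, %d distinct labels\n",
              object$n, num_clusters_from_labels(object$labels)))
  print(table(labels = object$labels))
  cat("\nMetrics per linkage (1 = perfect recovery):\n")
  print(object$metrics, row.names = FALSE)
  for (l in names(object$partitions)) {
    cat(sprintf("\nCross-tabulation (%s linkage):\n", l))
    print(table(cluster = object$partitions[[l]], label = object$labels))
  }
  invisible(object)
}

#' @export
plot.taxa_cluster <- function(x, linkage = names(x$dendrograms)[1], ...) {
  plot(x$dendrograms[[linkage]],
       main = sprintf("Agglomerative clustering (%s linkage)", linkage),
       xlab = "", sub = "", ...)
  stats::rect.hclust(x$dendrograms[[linkage]], k = x$k, border = "red3")
  invisible(x)
}

#' Read and write the framework's CSV files
#'
#' The distance CSV has molecule IDs as the header row and first column,
#' cell `(i, j)` holding the dissimilarity. The labels CSV has an `id`
#' column plus one or more label columns (e.g. `taxon` or
#' `phylum`/`class`/`order`). The feature CSV has columns `id`, `s`, `e`.
#' Dialect: comma-separated, dot decimal, UTF-8, header row.
#'
#' @param D Distance matrix; `path` a file path; `labels` a named vector or
#'   label data frame; `features` a feature data frame.
#' @param rank Label column to extract (default `"phylum"`, falls back to
#'   `"taxon"`).
#' @return Readers return the matrix / named vector / data frame; writers
#'   return `path` invisibly.
#' @name framework_csv
NULL

#' @rdname framework_csv
#' @export
write_distance_csv <- function(D, path) {
  utils::write.csv(as.data.frame(D), path)
  invisible(path)
}

#' @rdname framework_csv
#' @export
read_distance_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  D <- as.matrix(df)
  if (!identical(rownames(D), colnames(D)))
    stop("distance CSV row and column IDs differ")
  check_distance_matrix(D)
}

#' @rdname framework_csv
#' @export
write_labels_csv <- function(labels, path) {
  if (!is.data.frame(labels))
    labels <- data.frame(id = names(labels), taxon = as.character(labels))
  utils::write.csv(labels, path, row.names = FALSE)
  invisible(path)
}

#' @rdname framework_csv
#' @export
read_labels_csv <- function(path, rank = "phylum") {
  as_label_vector(utils::read.csv(path, check.names = FALSE), rank = rank)
}

#' @rdname framework_csv
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features[, c("id", "s", "e")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname framework_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot(all(c("id", "s", "e") %in% names(df)))
  df
}

#' Write a self-contained synthetic fixture tree
#'
#' Dumps a generated molecule set in the framework's input schema, one
#' format per sub-folder as in rRNA benchmark repositories: `bpseq/` and
#' `db/` with one file per molecule (headered dialect), plus a
#' `labels.csv`, a genus distance matrix `distances_genus.csv`, and a
#' `manifest.csv` with the metrics the pipeline reproduces on that matrix.
#' Byte-identical for identical `config` (all generators are seeded).
#'
#' @param config A [generator_config()].
#' @param out Output directory (created if missing).
#' @return Invisibly, the list of written paths.
#' @export
generate_fixtures <- function(config = generator_config(), out) {
  set <- gen_labeled_structures(config)
  dir.create(file.path(out, "bpseq"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "db"), recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (id in names(set$structures)) {
    s <- set$structures[[id]]
    p1 <- file.path(out, "bpseq", paste0(id, ".bpseq"))
    p2 <- file.path(out, "db", paste0(id, ".db"))
    writeLines(sub("\n$", "", write_bpseq(s, name = id)), p1)
    writeLines(sub("\n$", "", write_dotbracket(s, name = id)), p2)
    paths <- c(paths, p1, p2)
  }
  lab_path <- file.path(out, "labels.csv")
  write_labels_csv(set$labels, lab_path)
  D <- compute_distance_matrix(set$structures, method = "genus")
  dist_path <- file.path(out, "distances_genus.csv")
  write_distance_csv(D, dist_path)
  fit <- taxa_cluster(D, set$labels)
  man_path <- file.path(out, "manifest.csv")
  utils::write.csv(fit$metrics, man_path, row.names = FALSE)
  invisible(c(paths, lab_path, dist_path, man_path))
}
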
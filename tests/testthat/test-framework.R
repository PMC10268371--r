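make_set <- function() {
  list(
    n1 = parse_dotbracket("((...))"),
    n2 = parse_dotbracket("(((...)))"),
    pk = rna_structure(8, rbind(c(1, 4), c(3, 6)))
  )
}

test_that("genus distances over a mixed set form the expected matrix", {
  D <- compute_distance_matrix(make_set(), method = "genus")
  want <- rbind(c(0, 0, 1), c(0, 0, 1), c(1, 1, 0))
  dimnames(want) <- list(names(make_set()), names(make_set()))
  expect_equal(D, want)
  Do <- compute_distance_matrix(make_set(), method = "pskorder")
  expect_equal(unname(Do), unname(want))
})

test_that("identical molecules give the all-zero matrix for every method", {
  s <- gen_pseudoknotted_structure(generator_config(seed = 21))
  trio <- list(a = s, b = s, c = s)
  for (m in c("genus", "pskorder", "aspra", "rag2d")) {
    D <- compute_distance_matrix(trio, method = m)
    expect_equal(unname(D), matrix(0, 3, 3), tolerance = 1e-12)
  }
})

test_that("distance matrices survive the CSV round-trip", {
  pp <- gen_planted_partition(generator_config(seed = 13, n_molecules = 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_distance_csv(pp$distances, path)
  back <- read_distance_csv(path)
  expect_equal(back, pp$distances, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("a folder of mixed-format files is read and compared", {
  dir <- withr::local_tempdir()
  set <- make_set()
  writeLines(write_bpseq(set$n1, name = "n1"), file.path(dir, "n1.bpseq"))
  writeLines(write_ct(set$n2, name = "n2"), file.path(dir, "n2.ct"))
  writeLines(write_dotbracket(set$pk, name = "pk"), file.path(dir, "pk.db"))
  D <- compute_distance_matrix(dir, method = "genus")
  expect_setequal(rownames(D), c("n1", "n2", "pk"))
  expect_equal(D["n1", "pk"], 1)
  expect_equal(D["n1", "n2"], 0)
  # malformed files abort with the filename
  writeLines("1 A 5\n2 C 0\n3 G 0", file.path(dir, "bad.bpseq"))
  expect_error(compute_distance_matrix(dir, method = "genus"), "bad.bpseq")
})

test_that("the full pipeline recovers a separated planted taxonomy", {
  pp <- gen_planted_partition(generator_config(seed = 17, n_molecules = 21,
                                               n_taxa = 3))
  fit <- taxa_cluster(pp$distances, pp$labels)
  expect_s3_class(fit, "taxa_cluster")
  expect_equal(fit$k, 3L)
  expect_equal(nrow(fit$metrics), 3L)
  expect_true(all(as.matrix(fit$metrics[, -1]) == 1))
  expect_output(print(fit), "3 clusters")
})

test_that("one shared taxon label forces perfect scores", {
  pp <- gen_planted_partition(generator_config(seed = 19, n_molecules = 12,
                                               n_taxa = 1))
  fit <- taxa_cluster(pp$distances, pp$labels)
  expect_equal(fit$k, 1L)
  expect_true(all(as.matrix(fit$metrics[, -1]) == 1))
})

test_that("feature input and precomputed rag2d distances are equivalent", {
  set <- gen_labeled_structures(generator_config(seed = 23, n_molecules = 8,
                                                 n_taxa = 2))
  feats <- compute_feature_table(set$structures)
  D_feat <- features_to_distances(feats)
  D_direct <- compute_distance_matrix(set$structures, method = "rag2d")
  expect_equal(D_feat, D_direct, tolerance = 1e-12)
  fit1 <- taxa_cluster(D_feat, set$labels)
  fit2 <- taxa_cluster(D_direct, set$labels)
  expect_equal(fit1$metrics, fit2$metrics)
})

test_that("ID mismatches between labels and matrix are refused", {
  pp <- gen_planted_partition(generator_config(seed = 29, n_molecules = 6))
  bad <- pp$labels
  names(bad)[1] <- "STRANGER"
  expect_error(taxa_cluster(pp$distances, bad), "IDs")
  expect_error(taxa_cluster(pp$distances, pp$labels[-1]), "IDs")
  # labels may arrive as a data frame with a taxonomy-rank column
  df <- data.frame(id = names(pp$labels), phylum = unname(pp$labels))
  fit <- taxa_cluster(pp$distances, df)
  expect_equal(fit$k, num_clusters_from_labels(pp$labels))
  # ... and in shuffled order
  df2 <- df[rev(seq_len(nrow(df))), ]
  expect_equal(taxa_cluster(pp$distances, df2)$metrics, fit$metrics)
})

test_that("fixture trees are byte-stable and self-consistent", {
  cfg <- generator_config(seed = 31, n_molecules = 6, n_taxa = 2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_fixtures(cfg, d1)
  generate_fixtures(cfg, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # the manifest metrics reproduce when the pipeline is re-run from files
  labels <- read_labels_csv(file.path(d1, "labels.csv"), rank = "taxon")
  D <- read_distance_csv(file.path(d1, "distances_genus.csv"))
  fit <- taxa_cluster(D, labels)
  manifest <- utils::read.csv(file.path(d1, "manifest.csv"))
  expect_equal(fit$metrics$rand_index, manifest$rand_index, tolerance = 1e-9)
  expect_equal(fit$metrics$homogeneity, manifest$homogeneity, tolerance = 1e-9)
  # structures on disk reload to the generated ones, in both formats
  set <- gen_labeled_structures(cfg)
  s <- read_structure(file.path(d1, "bpseq", "M001.bpseq"))
  expect_equal(s$pairs, set$structures$M001$pairs)
  s_db <- read_structure(file.path(d1, "db", "M004.db"))
  expect_equal(s_db$pairs, set$structures$M004$pairs)
  # the format folders feed the distance step directly
  D_fx <- compute_distance_matrix(file.path(d1, "db"), method = "genus")
  expect_equal(unname(D_fx), unname(D))
})

test_that("labels CSV honours the taxonomy-rank column", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(id = c("a", "b"), phylum = c("P1", "P2"),
                   class = c("C1", "C1"))
  utils::write.csv(df, path, row.names = FALSE)
  expect_equal(unname(read_labels_csv(path, rank = "phylum")), c("P1", "P2"))
  expect_equal(unname(read_labels_csv(path, rank = "class")), c("C1", "C1"))
})
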
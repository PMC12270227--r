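random_matrix <- function(n = 30, p = 10, seed = 1, prefix = "f") {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("r", seq_len(n)),
                              paste0(prefix, seq_len(p))))
  m
}

test_that("zero-variance removal drops exactly the constant columns", {
  m <- random_matrix(20, 8, seed = 2)
  m[, c(2, 5, 7)] <- 3.14
  out <- drop_zero_variance(m)
  expect_setequal(reduction_provenance(out)$removed, c("f2", "f5", "f7"))
  expect_equal(ncol(out), 5)
  # no constant columns: identity
  m2 <- random_matrix(20, 5, seed = 3)
  expect_equal(drop_zero_variance(m2)[, ], m2, ignore_attr = TRUE)
  expect_error(drop_zero_variance(matrix(1, 5, 3)), "all features")
})

test_that("collinearity removal enforces its post-condition and is idempotent", {
  # duplicate columns: exactly one of the pair is removed
  m <- random_matrix(40, 5, seed = 4)
  m[, 2] <- m[, 1]
  out <- remove_collinear(m, 0.8)
  expect_equal(ncol(out), 4)
  expect_length(intersect(c("f1", "f2"), colnames(out)), 1)

  # correlated blocks: no remaining pair exceeds the cut (exhaustive check)
  set.seed(5)
  base <- matrix(rnorm(60 * 4), 60, 4)
  noisy <- base[, rep(1:4, each = 5)] + matrix(rnorm(60 * 20, sd = 0.3), 60)
  colnames(noisy) <- sprintf("g%02d", 1:20)
  red <- remove_collinear(noisy, 0.8)
  cc <- abs(cor(red)); diag(cc) <- 0
  expect_lte(max(cc), 0.8)
  # idempotence
  red2 <- remove_collinear(red, 0.8)
  expect_identical(colnames(red2), colnames(red))
  # provenance replay reproduces the retained set
  replay <- setdiff(colnames(noisy), reduction_provenance(red)$removed)
  expect_identical(colnames(red), replay)

  # independent columns: nothing removed
  big <- random_matrix(200, 15, seed = 6)
  expect_equal(ncol(remove_collinear(big, 0.8)), 15)
  expect_error(remove_collinear(big, 1.2), "r_cut")
})

test_that("condition concatenation doubles the feature axis and round-trips", {
  a <- random_matrix(10, 482, seed = 7)
  b <- random_matrix(10, 482, seed = 8)
  wide <- concat_conditions(a, b)
  expect_equal(ncol(wide), 964)
  expect_equal(nrow(wide), 10)
  # split back by suffix recovers both halves
  expect_equal(unname(wide[, grepl("_resting$", colnames(wide))]), unname(a))
  expect_equal(unname(wide[, grepl("_activated$", colnames(wide))]), unname(b))
  # mismatched row keys are refused
  b2 <- b; rownames(b2)[1] <- "zz"
  expect_error(concat_conditions(a, b2), "row keys differ")
})

test_that("the embedding has the contracted shape, determinism and separation", {
  set.seed(9)
  p1 <- rnorm(40, sd = 3); p2 <- rnorm(40, sd = 3)
  m <- rbind(matrix(rnorm(25 * 40), 25, 40) + rep(p1, each = 25),
             matrix(rnorm(25 * 40), 25, 40) + rep(p2, each = 25))
  rownames(m) <- paste0("r", 1:50); colnames(m) <- paste0("f", 1:40)
  e1 <- embed_fingerprints(m, n_components = 100)
  expect_equal(dim(e1), c(50, 100))
  e2 <- embed_fingerprints(m, n_components = 100)
  expect_identical(e1[, ], e2[, ])
  # well-separated planted groups stay separated
  sil <- cluster::silhouette(rep(1:2, each = 25), dist(e1))
  expect_gt(mean(sil[, 3]), 0.5)
  expect_error(embed_fingerprints(m[1:2, ]), "too few rows")
})

test_that("similarity matrices match a brute-force pairwise computation", {
  m <- random_matrix(10, 20, seed = 10)
  s <- similarity_matrix(m, "pearson")
  expect_equal(unname(s), oracle_pearson_similarity(m), tolerance = 1e-12)
  expect_equal(diag(s), setNames(rep(1, 10), rownames(m)))
  expect_equal(s, t(s))
  # identical rows similarity 1; opposite rows -1
  m2 <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(-1, -2, -3))
  s2 <- similarity_matrix(m2)
  expect_equal(s2["a", "b"], 1)
  expect_equal(s2["a", "c"], -1)
  # zero-variance row flagged missing
  m3 <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  s3 <- similarity_matrix(m3)
  expect_true(all(is.na(s3["b", ])))
  # euclidean variant is the distance matrix
  expect_equal(similarity_matrix(m, "euclidean"), as.matrix(dist(m)))
})

test_that("density clustering recovers planted groups and rejects noise", {
  ari <- vapply(1:10, function(s) {
    set.seed(s)
    g <- rbind(matrix(rnorm(20 * 6, 0, 0.15), 20),
               matrix(rnorm(20 * 6, 4, 0.15), 20),
               matrix(rnorm(20 * 6, -4, 0.15), 20))
    rownames(g) <- paste0("p", 1:60)
    lab <- cluster_hdbscan(as.matrix(dist(g)), min_cluster_size = 5,
                           input = "distance")
    mclust::adjustedRandIndex(rep(1:3, each = 20), lab)
  }, 0)
  expect_true(all(ari > 0.9))

  # pure noise is mostly labelled -1
  noise_frac <- vapply(1:5, function(s) {
    set.seed(100 + s)
    nz <- matrix(runif(60 * 5), 60); rownames(nz) <- paste0("n", 1:60)
    lab <- cluster_hdbscan(as.matrix(dist(nz)), min_cluster_size = 5,
                           input = "distance")
    mean(lab == -1)
  }, 0)
  expect_gt(median(noise_frac), 0.5)

  # deterministic: identical input, identical labelling
  set.seed(3)
  g <- rbind(matrix(rnorm(30 * 4), 30), matrix(rnorm(30 * 4, 5), 30))
  rownames(g) <- paste0("q", 1:60)
  d <- as.matrix(dist(g))
  expect_identical(cluster_hdbscan(d, input = "distance"),
                   cluster_hdbscan(d, input = "distance"))
  expect_error(cluster_hdbscan(d[1:3, 1:3], input = "distance"), "at least 5")
})

test_that("density clustering agrees with an independent reference implementation", {
  set.seed(99)
  g <- rbind(matrix(rnorm(20 * 5, 0, 0.15), 20),
             matrix(rnorm(20 * 5, 4, 0.15), 20),
             matrix(rnorm(25 * 5, -4, 0.15), 25),
             matrix(runif(8 * 5, -6, 6), 8))
  rownames(g) <- paste0("p", seq_len(nrow(g)))
  lab <- cluster_hdbscan(as.matrix(dist(g)), min_cluster_size = 5,
                         input = "distance")
  pts <- tempfile(fileext = ".tsv")
  write.table(g, pts, sep = "\t", col.names = FALSE, row.names = FALSE)
  script <- paste0(
    "import numpy as np\n",
    "from sklearn.cluster import HDBSCAN\n",
    "x = np.loadtxt('", pts, "')\n",
    "print(' '.join(map(str, HDBSCAN(min_cluster_size=5).fit(x).labels_)))\n")
  out <- suppressWarnings(system2("python", c("-c", shQuote(script)),
                                  stdout = TRUE, stderr = FALSE))
  sk <- as.integer(strsplit(tail(out, 1), " ")[[1]])
  expect_gt(mclust::adjustedRandIndex(lab, sk), 0.9)
})

test_that("hierarchical clustering matches brute-force complete linkage", {
  m <- random_matrix(6, 12, seed = 12)
  h <- cluster_hierarchical(m, "rows")
  d <- as.dist(1 - cor(t(m)))
  expect_equal(sort(h$height), oracle_complete_linkage_heights(d))
  # identical pair merges first
  m2 <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4) * 2, c = c(4, 1, -2, 7))
  h2 <- cluster_hierarchical(m2, "rows")  # a and b perfectly correlated
  expect_setequal(h2$labels[-h2$merge[1, ]], c("a", "b"))
  # leaf order is stable across runs
  expect_identical(attr(cluster_hierarchical(m, "rows"), "leaf_order"),
                   attr(cluster_hierarchical(m, "rows"), "leaf_order"))
})

test_that("heatmap export round-trips values and honours compartment sort", {
  m <- random_matrix(8, 10, seed = 13)
  colnames(m) <- paste0(rep(c("Nuc_", "ER_"), 5), "v", 1:10)
  rt <- cluster_hierarchical(m, "rows")
  ct <- cluster_hierarchical(m, "columns")
  prefix <- tempfile("hm")
  export_heatmap(m, rt, ct, path_prefix = prefix)
  back <- read.delim(paste0(prefix, "_matrix.tsv"), check.names = FALSE)
  expect_equal(sort(back$id), sort(rownames(m)))
  m_back <- as.matrix(back[, -1]); rownames(m_back) <- back$id
  expect_equal(m_back[rownames(m), colnames(m)], m)
  # compartment sort groups prefixes contiguously
  export_heatmap(m, rt, ct, path_prefix = paste0(prefix, "c"),
                 compartment_sort = TRUE)
  back2 <- read.delim(paste0(prefix, "c_matrix.tsv"), check.names = FALSE)
  comp <- sub("_.*$", "", colnames(back2)[-1])
  expect_equal(comp, rep(unique(comp), each = 5))
  expect_error(export_heatmap(m[0, ], NULL, NULL), "empty")
  # mismatched tree leaves
  expect_error(export_heatmap(m[-1, ], rt, NULL, tempfile()), "leaves")
})

test_that("planted two-group structure survives reduce, embed and cluster", {
  ari <- vapply(1:10, function(s) {
    set.seed(s)
    pattern <- rnorm(60)              # class means 2 SD apart
    m <- rbind(sweep(matrix(rnorm(15 * 60), 15, 60), 2, -pattern, `+`),
               sweep(matrix(rnorm(15 * 60), 15, 60), 2, pattern, `+`))
    rownames(m) <- paste0("r", 1:30)
    colnames(m) <- paste0("f", 1:60)
    m <- cbind(m, matrix(5, 30, 3, dimnames = list(NULL, paste0("z", 1:3))))
    red <- remove_collinear(drop_zero_variance(m), 0.8)
    emb <- embed_fingerprints(red, n_components = 10)
    lab <- cluster_hdbscan(similarity_matrix(emb, "pearson"),
                           min_cluster_size = 5)
    mclust::adjustedRandIndex(rep(1:2, each = 15), lab)
  }, 0)
  expect_gt(median(ari), 0.8)
})
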
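test_that("k-means groups two separated pairs with the closed-form WSS", {
  Y <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  rownames(Y) <- paste0("s", 1:4)
  cl <- kmeans_cluster(Y, 2, seed = 1)
  expect_identical(unname(cl$labels[1]), unname(cl$labels[2]))
  expect_identical(unname(cl$labels[3]), unname(cl$labels[4]))
  expect_false(cl$labels[1] == cl$labels[3])
  # each pair: two points at distance 1 -> WSS = 2 * (0.5^2) per pair
  expect_equal(cl$wss, 2 * 2 * 0.25)
})

test_that("k bounds are enforced and labels start at zero", {
  b <- blob_embedding(n_per = 5)
  expect_error(kmeans_cluster(b$coords, 15), "\\[2, 14\\]")
  cl <- kmeans_cluster(b$coords, 14, seed = 1)
  expect_identical(min(cl$labels), 0L)
  expect_identical(sort(unique(unname(cl$labels))), 0:13)
})

test_that("k-means separates three planted blobs perfectly", {
  b <- blob_embedding(n_per = 40, seed = 2)
  cl <- kmeans_cluster(b$coords, 3, seed = 3)
  expect_ari(cl$labels, b$labels, 1)
  cl2 <- kmeans_cluster(b$coords, 3, seed = 3)
  expect_identical(cl$labels, cl2$labels)             # determinism
})

test_that("elbow selection finds three blobs and flags a single blob", {
  b <- blob_embedding(n_per = 50, sd = 0.5, seed = 4)
  k <- elbow_select_k(b$coords, seed = 1)
  expect_identical(as.integer(k), 3L)
  expect_false(attr(k, "low_confidence"))
  set.seed(5)
  single <- matrix(rnorm(200), 100, 2)
  expect_message(k1 <- elbow_select_k(single, seed = 1), "no clear elbow")
  expect_identical(as.integer(k1), 2L)
  expect_true(attr(k1, "low_confidence"))
})

test_that("elbow selection is invariant to duplicating the dataset", {
  b <- blob_embedding(n_per = 30, seed = 6)
  k1 <- elbow_select_k(b$coords, seed = 1)
  dup <- rbind(b$coords, b$coords + 1e-9)
  rownames(dup) <- sprintf("d%03d", seq_len(nrow(dup)))
  k2 <- elbow_select_k(dup, seed = 1)
  expect_identical(as.integer(k1), as.integer(k2))
})

test_that("elbow selection rejects a degenerate embedding", {
  Y <- matrix(1, 20, 2)
  expect_error(elbow_select_k(Y), "degenerate")
})

test_that("the kNN graph has the right degrees and is isometry invariant", {
  set.seed(7)
  Y <- matrix(rnorm(100), 50, 2)
  rownames(Y) <- sprintf("s%02d", 1:50)
  g <- knn_graph(Y, 5)
  expect_true(all(igraph::degree(g) >= 5))
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  Yr <- Y %*% R + 3
  rownames(Yr) <- rownames(Y)
  gr <- knn_graph(Yr, 5)
  expect_identical(igraph::as_edgelist(g), igraph::as_edgelist(gr))
  expect_error(knn_graph(Y, 50), "n_neighbors")
})

test_that("kNN graph edges agree with an explicit full-sort neighbour list", {
  set.seed(8)
  Y <- matrix(rnorm(100), 50, 2)
  g <- knn_graph(Y, 7)
  D <- as.matrix(dist(Y))
  el <- igraph::as_edgelist(g, names = FALSE)
  want <- matrix(FALSE, 50, 50)
  for (i in 1:50) {
    nb <- setdiff(order(D[i, ], seq_len(50)), i)[1:7]
    want[i, nb] <- TRUE
  }
  want <- want | t(want)
  got <- matrix(FALSE, 50, 50)
  got[el] <- TRUE; got <- got | t(got)
  expect_identical(got, want)
})

test_that("Leiden finds disconnected cliques and merges at low resolution", {
  g <- igraph::disjoint_union(igraph::make_full_graph(10),
                              igraph::make_full_graph(10))
  cl <- leiden_cluster(g, resolution = 1, seed = 1)
  expect_identical(length(unique(cl$labels)), 2L)
  expect_identical(unname(cl$labels), rep(0:1, each = 10))
  connected <- igraph::make_lattice(c(5, 4))
  cl0 <- leiden_cluster(connected, resolution = 0.01, seed = 1)
  expect_identical(length(unique(cl0$labels)), 1L)
  expect_error(leiden_cluster(igraph::make_empty_graph(0), 1), "empty")
})

test_that("Leiden recovers a planted two-blob embedding exactly", {
  b <- blob_embedding(n_per = 20, centers = rbind(c(0, 0), c(10, 0)), seed = 9)
  cl <- leiden_cluster(knn_graph(b$coords, 15), resolution = 1, seed = 2)
  expect_ari(cl$labels, b$labels, 1)
})

test_that("community count does not increase as resolution decreases", {
  b <- blob_embedding(n_per = 50, seed = 10)
  g <- knn_graph(b$coords, 15)
  n_high <- length(unique(leiden_cluster(g, 1, seed = 3)$labels))
  n_low <- length(unique(leiden_cluster(g, 0.05, seed = 3)$labels))
  expect_lte(n_low, n_high)
})

test_that("cluster labels are stable under sample permutation (up to relabel)", {
  b <- blob_embedding(n_per = 30, seed = 11)
  cl <- kmeans_cluster(b$coords, 3, seed = 4)
  perm <- sample(nrow(b$coords))
  clp <- kmeans_cluster(b$coords[perm, ], 3, seed = 4)
  expect_ari(clp$labels, cl$labels[perm], 1)
})
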
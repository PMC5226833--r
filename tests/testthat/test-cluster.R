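test_that("arrows are built per inter-basin transition with the right dimension", {
  o <- rep(c(1L, 2L), 300)
  x <- c(rep(1L, 199), rep(2L, 200), rep(1L, 200))
  comps <- decompose_trace(o, x)
  arr <- kinetic_arrows(comps)
  expect_equal(nrow(arr), 2)                 # labels (1,2,1) -> 2 arrows
  expect_equal(ncol(arr), 2 * 2 * (2 - 1))   # 2 N (N-1) with N = 2
  info <- attr(arr, "info")
  expect_equal(info$from_label, c(1L, 2L))
  expect_equal(info$to_label, c(2L, 1L))
  # N = 4 components give 24-dimensional arrows
  o4 <- rep(c(1L, 2L, 3L, 4L), 100)
  x4 <- c(rep(1L, 200), rep(2L, 199))
  arr4 <- kinetic_arrows(decompose_trace(o4, x4))
  expect_equal(ncol(arr4), 24)
})

test_that("the mirror operator swaps halves and is an involution", {
  v <- 1:8
  expect_equal(mirror_arrows(v), c(5:8, 1:4))
  expect_equal(mirror_arrows(mirror_arrows(v)), v)
  M <- matrix(runif(24 * 3), 3, 24)
  expect_equal(mirror_arrows(mirror_arrows(M)), M)
  # reverse transition with identical rates equals the mirror of the forward
  o <- rep(c(1L, 2L), 300)
  x <- c(rep(1L, 299), rep(2L, 300))
  comps <- decompose_trace(o, x)
  comps2 <- comps
  comps2$label <- rev(comps2$label)
  comps2[, c("k1.2", "k2.1")] <- comps2[rev(seq_len(2)), c("k1.2", "k2.1")]
  fwd <- kinetic_arrows(comps)
  rev_ <- kinetic_arrows(comps2)
  expect_equal(as.numeric(rev_[1, ]), as.numeric(mirror_arrows(fwd[1, ])),
               tolerance = 1e-12)
})

test_that("centroid pairing recovers constructed mirror pairs", {
  # two exact mirrors -> D_c = 0
  c1 <- c(1, 2, 3, 4)
  cents <- rbind(c1, mirror_arrows(c1))
  pc <- pair_centroids(cents)
  expect_equal(pc$D_c, 0, tolerance = 1e-12)
  expect_error(pair_centroids(cents[1, , drop = FALSE]), "even")

  # 4 centroids as two mirror pairs plus noise: brute force over 3 matchings
  set.seed(3)
  a <- rnorm(4); b <- rnorm(4)
  cents4 <- rbind(a, mirror_arrows(a) + 0.01, b, mirror_arrows(b) - 0.01)
  pc4 <- pair_centroids(cents4)
  got <- apply(pc4$pairs, 1, sort)
  expect_true(all(apply(got, 2, paste, collapse = "-") %in% c("1-2", "3-4")))
})

test_that("double-factorial enumeration stays exact and tractable", {
  count_matchings <- function(K) if (K <= 0) 1 else (K - 1) * count_matchings(K - 2)
  expect_equal(count_matchings(12), 10395)
  # the recursive search agrees with direct evaluation on a random case
  set.seed(5)
  cents <- matrix(rnorm(6 * 4), 6, 4)
  pc <- pair_centroids(cents)
  d2 <- function(i, j) sum((cents[i, ] - mirror_arrows(cents[j, ]))^2)
  # all 15 matchings of 6 elements
  ms <- list(rbind(c(1,2),c(3,4),c(5,6)), rbind(c(1,2),c(3,5),c(4,6)),
             rbind(c(1,2),c(3,6),c(4,5)), rbind(c(1,3),c(2,4),c(5,6)),
             rbind(c(1,3),c(2,5),c(4,6)), rbind(c(1,3),c(2,6),c(4,5)),
             rbind(c(1,4),c(2,3),c(5,6)), rbind(c(1,4),c(2,5),c(3,6)),
             rbind(c(1,4),c(2,6),c(3,5)), rbind(c(1,5),c(2,3),c(4,6)),
             rbind(c(1,5),c(2,4),c(3,6)), rbind(c(1,5),c(2,6),c(3,4)),
             rbind(c(1,6),c(2,3),c(4,5)), rbind(c(1,6),c(2,4),c(3,5)),
             rbind(c(1,6),c(2,5),c(3,4)))
  costs <- sapply(ms, function(m) sum(apply(m, 1, function(p) d2(p[1], p[2]))))
  expect_equal(pc$D_c, 2 / 6 * min(costs), tolerance = 1e-12)
})

test_that("pairing score vanishes on exact mirror clusters", {
  base <- c(0.5, -1, 2, 0.3)
  arrows <- rbind(c(base, mirror_arrows(base)[1:0]),  # placeholder removed below
                  NULL)
  fwd <- matrix(rep(c(base, -base), 5), 5, 8, byrow = TRUE)
  bwd <- mirror_arrows(fwd)
  arr <- rbind(fwd, bwd)
  asg <- rep(1:2, each = 5)
  pc <- pair_centroids(rbind(colMeans(fwd), colMeans(bwd)))
  expect_equal(pairing_score(arr, asg, pc$pairs), 0, tolerance = 1e-12)
  # single-element clusters reduce to the centroid distance
  arr1 <- rbind(fwd[1, ], bwd[1, ] + 0.3)
  pc1 <- pair_centroids(arr1)
  expect_equal(pairing_score(arr1, c(1L, 2L), pc1$pairs),
               2 / 2 * sqrt(sum((arr1[1, ] - mirror_arrows(arr1[2, ]))^2)),
               tolerance = 1e-12)
})

test_that("k-means recovers well-separated arrow clusters", {
  set.seed(11)
  centers <- matrix(rnorm(6 * 8, sd = 4), 6, 8)
  X <- do.call(rbind, lapply(1:6, function(k)
    sweep(matrix(rnorm(20 * 8, 0, 0.05), 20, 8), 2, centers[k, ], "+")))
  truth <- rep(1:6, each = 20)
  km <- kmeans_arrows(X, 6, n_init = 20, seed = 2)
  # perfect recovery up to label permutation
  expect_equal(length(unique(paste(truth, km$cluster))), 6)
  # K = n gives zero inertia: every point its own centroid
  km_all <- kmeans_arrows(X[1:8, ], 8, n_init = 5, seed = 3)
  expect_equal(sort(km_all$size), rep(1L, 8), ignore_attr = TRUE)
  expect_error(kmeans_arrows(X, nrow(X) + 1, n_init = 2), "exceeds")
  # city-block mode returns the same structure
  km_l1 <- kmeans_arrows(X, 6, n_init = 10, seed = 4, metric = "cityblock")
  expect_equal(length(unique(paste(truth, km_l1$cluster))), 6)
})

test_that("cluster-count selection applies the minimum-size rule", {
  set.seed(21)
  base <- matrix(rnorm(2 * 6, sd = 3), 2, 6)
  arr <- mirror_arrow_set(base[1, 1:3], base[1, 4:6], n = 15, sd = 0.05)
  arr <- rbind(arr, mirror_arrow_set(base[2, 1:3], base[2, 4:6], n = 15,
                                     sd = 0.05, seed = 2))
  scan <- select_clusters(arr, K_range = c(2, 4), min_cluster_size = 10,
                          n_init = 50, seed = 5)
  expect_equal(scan$K_star, 4)   # two bidirectional paths -> 4 clusters
  expect_true(all(scan$table$D >= 0))
  # a size floor larger than any cluster leaves K* unset
  scan2 <- select_clusters(arr, K_range = c(2, 4), min_cluster_size = 1000,
                           n_init = 20, seed = 5)
  expect_true(is.na(scan2$K_star))
  expect_error(select_clusters(arr, K_range = c(3)), "even")
})

test_that("a single bidirectional path clusters into one mirror pair", {
  arr <- mirror_arrow_set(c(-1, 2, 0.5), c(1, -2, 3), n = 20, sd = 0.05)
  scan <- select_clusters(arr, K_range = c(2, 4), min_cluster_size = 10,
                          n_init = 50, seed = 9)
  expect_equal(scan$K_star, 2)
  g <- landscape_graph(scan)
  expect_equal(nrow(g$edges), 1)
  expect_false(any(g$edges$self_loop))
})

test_that("landscape graph flags coincident before/after centroids", {
  # arrows whose before and after blocks coincide -> suspicious self-loop
  arr <- mirror_arrow_set(c(1, 2, 3), c(1, 2, 3), n = 12, sd = 1e-9)
  scan <- select_clusters(arr, K_range = 2, min_cluster_size = 5,
                          n_init = 10, seed = 3)
  expect_warning(g <- landscape_graph(scan), "self-loop")
  expect_true(all(g$edges$self_loop))
})

test_that("clustering is invariant to arrow input order at fixed seed", {
  arr <- mirror_arrow_set(c(-1, 2, 0.5), c(1, -2, 3), n = 15, sd = 0.05)
  s1 <- select_clusters(arr, K_range = 2, n_init = 20, seed = 4)
  perm <- sample(nrow(arr))
  s2 <- select_clusters(arr[perm, ], K_range = 2, n_init = 20, seed = 4)
  expect_equal(s1$table$D, s2$table$D, tolerance = 1e-9)
})
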
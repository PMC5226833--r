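#' Kinetic arrows from consecutive components
#'
#' Every adjacent pair of components with differing internal-state labels in a
#' trace marks one inter-basin transition. Its kinetic arrow is the
#' `2 N (N-1)`-dimensional vector of log off-diagonal transition rates: the
#' `N (N-1)` "before" rates of the earlier component followed by the "after"
#' rates of the later one, in fixed lexicographic `(a, b)` order. A middle
#' component contributes to both the arrow entering it and the arrow leaving
#' it. Traces with a single component contribute no arrows.
#'
#' @param components a `"dcmm_components"` data frame from [decompose_trace()], or a
#'   list of them (one per trace); components must be time-ordered within each
#'   trace.
#' @return Matrix of class `"kinetic_arrows"` (rows = arrows, columns =
#'   `log_k<a>.<b>.bf` then `log_k<a>.<b>.af`) with an `"info"` attribute
#'   data frame (`trace_id`, `from_label`, `to_label`).
#' @export
kinetic_arrows <- function(components) {
  if (is.data.frame(components)) components <- list(components)
  k_names <- grep("^k[0-9]+\\.[0-9]+$", names(components[[1]]), value = TRUE)
  arrows <- list()
  info <- list()
  for (comp in components) {
    stopifnot(all(k_names %in% names(comp)))
    for (tid in unique(comp$trace_id)) {
      cc <- comp[comp$trace_id == tid, , drop = FALSE]
      cc <- cc[order(cc$start), , drop = FALSE]
      if (nrow(cc) < 2) next
      for (i in seq_len(nrow(cc) - 1L)) {
        if (cc$label[i] == cc$label[i + 1L]) next
        v <- log(as.numeric(c(cc[i, k_names], cc[i + 1L, k_names])))
        arrows[[length(arrows) + 1L]] <- v
        info[[length(info) + 1L]] <-
          data.frame(trace_id = tid, from_label = cc$label[i],
                     to_label = cc$label[i + 1L])
      }
    }
  }
  M <- if (length(arrows)) do.call(rbind, arrows) else
    matrix(numeric(0), 0, 2 * length(k_names))
  colnames(M) <- c(paste0("log_", k_names, ".bf"),
                   paste0("log_", k_names, ".af"))
  structure(M, info = if (length(info)) do.call(rbind, info) else NULL,
            class = c("kinetic_arrows", class(M)))
}

#' Mirror operator on kinetic arrows
#'
#' Swaps the "before" and "after" halves of an arrow. The reverse of an
#' inter-basin transition equals the mirror of the forward arrow, so at
#' equilibrium (detailed balance) every arrow cluster should have an
#' antiparallel partner close to its mirror. The operator is an involution.
#'
#' @param arrows a vector or matrix of arrows (columns split evenly into
#'   before/after blocks).
#' @return The mirrored vector or matrix.
#' @export
mirror_arrows <- function(arrows) {
  if (is.matrix(arrows)) {
    d <- ncol(arrows)
    arrows[, c((d / 2 + 1):d, 1:(d / 2)), drop = FALSE]
  } else {
    d <- length(arrows)
    arrows[c((d / 2 + 1):d, 1:(d / 2))]
  }
}

kmeans_l1 <- function(X, K, n_init, iter_max = 100) {
  best <- NULL
  n <- nrow(X)
  for (r in seq_len(n_init)) {
    centers <- X[sample.int(n, K), , drop = FALSE]
    assign_old <- rep(0L, n)
    for (it in seq_len(iter_max)) {
      d <- sapply(seq_len(K), function(k)
        rowSums(abs(sweep(X, 2, centers[k, ]))))
      assign_new <- max.col(-d, ties.method = "first")
      for (k in seq_len(K)) {
        if (!any(assign_new == k)) assign_new[which.max(d[, k])] <- k
        centers[k, ] <- apply(X[assign_new == k, , drop = FALSE], 2, stats::median)
      }
      if (identical(assign_new, assign_old)) break
      assign_old <- assign_new
    }
    cost <- sum(abs(X - centers[assign_old, , drop = FALSE]))
    if (is.null(best) || cost < best$cost)
      best <- list(cluster = assign_old, centers = centers, cost = cost)
  }
  best
}

#' k-means clustering of kinetic arrows
#'
#' Best-inertia solution over `n_init` random initializations, with
#' squared-Euclidean distance by default or city-block (L1, cluster medians)
#' as a robustness check.
#'
#' @param arrows arrow matrix from [kinetic_arrows()].
#' @param K number of clusters (`K <= nrow(arrows)`).
#' @param n_init number of random initializations (default 200; raise toward
#'   2e4 for publication-grade runs).
#' @param seed optional integer seed.
#' @param metric `"sqeuclidean"` (default) or `"cityblock"`.
#' @return List with `cluster` (assignments), `centers`, `size`.
#' @export
kmeans_arrows <- function(arrows, K, n_init = 200, seed = NULL,
                          metric = c("sqeuclidean", "cityblock")) {
  metric <- match.arg(metric)
  X <- unclass(arrows)
  attr(X, "info") <- NULL
  if (K > nrow(X)) stop("K exceeds the number of arrows", call. = FALSE)
  if (K > nrow(unique(X)))
    stop("K exceeds the number of distinct arrows", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (metric == "cityblock") {
    fit <- kmeans_l1(X, K, n_init)
    return(list(cluster = fit$cluster, centers = fit$centers,
                size = tabulate(fit$cluster, K)))
  }
  fit <- tryCatch(
    suppressWarnings(kmeans(X, centers = K, nstart = n_init, iter.max = 100)),
    error = function(e)
      suppressWarnings(kmeans(X, centers = K, nstart = n_init, iter.max = 100,
                              algorithm = "Lloyd")))
  list(cluster = fit$cluster, centers = fit$centers, size = fit$size)
}

# Minimal-cost perfect matching of 1..K under symmetric cost matrix d2,
# by exhaustive recursion over the (K-1)!! pairings.
best_matching <- function(d2) {
  K <- nrow(d2)
  rec <- function(avail) {
    if (length(avail) == 0) return(list(cost = 0, pairs = NULL))
    i <- avail[1]
    best <- NULL
    for (j in avail[-1]) {
      sub <- rec(setdiff(avail, c(i, j)))
      cost <- d2[i, j] + sub$cost
      if (is.null(best) || cost < best$cost)
        best <- list(cost = cost, pairs = rbind(c(i, j), sub$pairs))
    }
    best
  }
  rec(seq_len(K))
}

#' Antiparallel pairing of arrow-cluster centroids
#'
#' Searches all perfect matchings of the `K` centroids into `K/2` pairs
#' (exhaustive over the `(K-1)!!` pairings) for the one minimizing the
#' centroid pairing distance
#' `D_c(K) = (2/K) * sum over matched pairs of ||C_i - mirror(C_j)||^2`.
#'
#' @param centroids `K x d` matrix of cluster centroids (`K` even).
#' @return List with `pairs` (a `K/2 x 2` matrix) and `D_c`.
#' @export
pair_centroids <- function(centroids) {
  K <- nrow(centroids)
  if (K %% 2 != 0)
    stop("centroid pairing requires an even number of clusters", call. = FALSE)
  d2 <- matrix(0, K, K)
  for (i in seq_len(K))
    for (j in seq_len(K))
      d2[i, j] <- sum((centroids[i, ] - mirror_arrows(centroids[j, ]))^2)
  m <- best_matching(d2)
  list(pairs = m$pairs, D_c = 2 / K * m$cost)
}

#' Element-level pairing score of a clustering
#'
#' For each matched cluster pair, averages the distance between every element
#' of one cluster and the mirror of every element of the other;
#' `D(K) = (2/K) * sum over matched pairs of <d_ij>`. The optimal cluster
#' count minimizes `D(K)`.
#'
#' @param arrows arrow matrix.
#' @param assignment integer cluster assignment per arrow.
#' @param pairs matched pairs from [pair_centroids()].
#' @return The pairing score `D`.
#' @export
pairing_score <- function(arrows, assignment, pairs) {
  X <- unclass(arrows)
  attr(X, "info") <- NULL
  K <- 2L * nrow(pairs)
  total <- 0
  for (p in seq_len(nrow(pairs))) {
    Ai <- X[assignment == pairs[p, 1], , drop = FALSE]
    Aj <- mirror_arrows(X[assignment == pairs[p, 2], , drop = FALSE])
    cross <- outer(rowSums(Ai^2), rowSums(Aj^2), "+") - 2 * tcrossprod(Ai, Aj)
    total <- total + mean(sqrt(pmax(cross, 0)))
  }
  2 / K * total
}

#' Scan cluster counts and select the kinetic connectivity
#'
#' For each even candidate `K`, clusters the arrows, finds the best
#' antiparallel centroid pairing, and computes the element-level pairing score
#' `D(K)`. The selected `K*` minimizes `D(K)` among solutions whose clusters
#' all contain at least `min_cluster_size` arrows; smaller solutions are
#' reported but ineligible (a minimum at very large `K` with tiny clusters is
#' statistically meaningless).
#'
#' @param arrows arrow matrix from [kinetic_arrows()].
#' @param K_range even candidate cluster counts (default `seq(2, 14, 2)`,
#'   truncated to the number of arrows).
#' @param min_cluster_size smallest admissible cluster (default 10).
#' @param n_init k-means initializations per `K` (default 200).
#' @param seed optional integer seed.
#' @param metric distance metric, see [kmeans_arrows()].
#' @return Object of class `"arrow_cluster_scan"`: per-K table (`K`, `D_c`,
#'   `D`, `min_size`, `eligible`), `K_star` (`NA` if no eligible `K`), and
#'   per-K `clusterings` (assignment, centers, pairs).
#' @export
select_clusters <- function(arrows, K_range = seq(2, 14, 2),
                            min_cluster_size = 10, n_init = 200, seed = NULL,
                            metric = "sqeuclidean") {
  if (any(K_range %% 2 != 0))
    stop("cluster counts must be even (antiparallel pairing)", call. = FALSE)
  K_range <- K_range[K_range <= nrow(arrows)]
  if (length(K_range) == 0) stop("no feasible cluster count", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tab <- data.frame(K = K_range, D_c = NA_real_, D = NA_real_,
                    min_size = NA_integer_, eligible = FALSE)
  clusterings <- vector("list", length(K_range))
  for (i in seq_along(K_range)) {
    K <- K_range[i]
    km <- kmeans_arrows(arrows, K, n_init = n_init, metric = metric)
    pc <- pair_centroids(km$centers)
    tab$D_c[i] <- pc$D_c
    tab$D[i] <- pairing_score(arrows, km$cluster, pc$pairs)
    tab$min_size[i] <- min(km$size)
    tab$eligible[i] <- min(km$size) >= min_cluster_size
    clusterings[[i]] <- list(cluster = km$cluster, centers = km$centers,
                             size = km$size, pairs = pc$pairs)
  }
  K_star <- if (any(tab$eligible))
    tab$K[tab$eligible][which.min(tab$D[tab$eligible])] else NA_integer_
  structure(list(table = tab, K_star = K_star, clusterings = clusterings,
                 K_range = K_range),
            class = "arrow_cluster_scan")
}

#' @export
print.arrow_cluster_scan <- function(x, ...) {
  cat("Kinetic-arrow cluster scan (antiparallel pairing)\n")
  print(transform(x$table, D_c = signif(D_c, 4), D = signif(D, 4)),
        row.names = FALSE)
  cat(sprintf("Selected K* = %s\n", x$K_star))
  invisible(x)
}

#' @export
plot.arrow_cluster_scan <- function(x, ...) {
  plot(x$table$K, x$table$D, type = "b", pch = ifelse(x$table$eligible, 19, 1),
       xlab = "number of clusters K", ylab = "pairing score D(K)", ...)
  if (!is.na(x$K_star))
    graphics::abline(v = x$K_star, lty = 2, col = "firebrick")
  invisible(x)
}

#' Kinetic connectivity graph from matched arrow clusters
#'
#' Each matched cluster pair is one bidirectional kinetic path between two
#' basins of the conformational landscape. Edge endpoints carry the centroid
#' "before" and "after" rates; a pair whose before/after centroid blocks
#' coincide is flagged as a suspicious self-loop. Optionally, endpoints are
#' merged into `n_basins` nodes by complete-linkage clustering of their rate
#' signatures.
#'
#' @param scan an `"arrow_cluster_scan"` from [select_clusters()].
#' @param K cluster count to use (default `scan$K_star`).
#' @param n_basins optional number of basins to merge endpoints into.
#' @param loop_tol distance below which a pair's before/after centroids are
#'   considered coincident (default 1e-6).
#' @return List of class `"kinetic_graph"`: `nodes` (id and log-rate
#'   signature) and `edges` (`from`, `to`, member clusters, sizes,
#'   `self_loop`).
#' @export
landscape_graph <- function(scan, K = scan$K_star, n_basins = NULL,
                            loop_tol = 1e-6) {
  stopifnot(inherits(scan, "arrow_cluster_scan"))
  if (is.na(K)) stop("no eligible cluster count selected", call. = FALSE)
  cl <- scan$clusterings[[match(K, scan$K_range)]]
  pairs <- cl$pairs
  d <- ncol(cl$centers)
  bf <- seq_len(d / 2)
  endpoints <- list()
  edges <- NULL
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    u <- (cl$centers[i, bf] + cl$centers[j, -bf]) / 2
    v <- (cl$centers[i, -bf] + cl$centers[j, bf]) / 2
    endpoints[[2 * p - 1]] <- u
    endpoints[[2 * p]] <- v
    self_loop <- sqrt(sum((cl$centers[i, bf] - cl$centers[i, -bf])^2)) < loop_tol
    edges <- rbind(edges, data.frame(
      from = 2 * p - 1, to = 2 * p, cluster_i = i, cluster_j = j,
      n_i = cl$size[i], n_j = cl$size[j], self_loop = self_loop))
  }
  E <- do.call(rbind, endpoints)
  if (!is.null(n_basins) && n_basins < nrow(E)) {
    grp <- stats::cutree(stats::hclust(stats::dist(E), method = "complete"),
                         k = n_basins)
    edges$from <- grp[edges$from]
    edges$to <- grp[edges$to]
    sig <- do.call(rbind, lapply(seq_len(n_basins), function(g)
      colMeans(E[grp == g, , drop = FALSE])))
    nodes <- data.frame(id = seq_len(n_basins))
    nodes <- cbind(nodes, as.data.frame(sig))
  } else {
    nodes <- data.frame(id = seq_len(nrow(E)))
    nodes <- cbind(nodes, as.data.frame(E))
  }
  if (any(edges$self_loop))
    warning("a matched pair has coincident before/after centroids (self-loop)",
            call. = FALSE)
  structure(list(nodes = nodes, edges = edges, K = K),
            class = "kinetic_graph")
}

#' @export
print.kinetic_graph <- function(x, ...) {
  cat(sprintf("Kinetic connectivity graph: %d basins, %d bidirectional paths (K = %d clusters)\n",
              length(unique(c(x$edges$from, x$edges$to))), nrow(x$edges), x$K))
  print(x$edges[, c("from", "to", "cluster_i", "cluster_j", "n_i", "n_j",
                    "self_loop")], row.names = FALSE)
  invisible(x)
}
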
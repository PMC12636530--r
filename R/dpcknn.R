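# Clustering-based cell-line feature (CCF) encoder: a k-nearest-neighbour
# density-peaks clustering (DPC-KNN) variant compresses the L x D_P enriched
# gene matrix G into |C| cluster-level rows.
#
# Local density uses the mean *squared* Euclidean distance to the k nearest
# neighbours (self excluded); the separation indicator uses plain Euclidean
# distance. Cluster centers are the genes with the largest density x
# separation products; remaining genes join the nearest center.

#' Local density of each gene
#'
#' `rho_i = exp(-(1/k) * sum_{j in KNN(i)} ||g_i - g_j||^2)` with the k
#' nearest neighbours taken over squared Euclidean distance, excluding the
#' gene itself. Densities lie in (0, 1].
#'
#' @param G numeric matrix, `L` genes x `D_P` channels.
#' @param k neighbour count, `1 <= k < L`.
#' @return numeric vector of length `L`.
#' @export
local_density <- function(G, k) {
  L <- nrow(G)
  if (k >= L || k < 1) stop("k must satisfy 1 <= k < L (k=", k, ", L=", L, ")")
  d2 <- as.matrix(stats::dist(G))^2
  rho <- vapply(seq_len(L), function(i) {
    nb <- sort(d2[i, -i], partial = k)[seq_len(k)]
    exp(-mean(nb))
  }, numeric(1))
  rho
}

#' Separation distance of each gene
#'
#' For genes with at least one strictly denser gene, the minimum Euclidean
#' distance to any such gene; for the density maxima, the maximum distance
#' to any gene.
#'
#' @param G numeric matrix, `L x D_P` with `L >= 2`.
#' @param rho densities from [local_density()] on the same `G`.
#' @return numeric vector of length `L`.
#' @export
separation_distance <- function(G, rho) {
  L <- nrow(G)
  if (L < 2) stop("separation distance needs at least 2 genes")
  dm <- as.matrix(stats::dist(G))
  vapply(seq_len(L), function(i) {
    denser <- rho > rho[i]
    if (any(denser)) min(dm[i, denser]) else max(dm[i, ])
  }, numeric(1))
}

#' Select cluster centers by density x separation score
#'
#' Returns the indices of the `n_clusters` largest `rho * delta` products;
#' ties break toward the lower index.
#'
#' @param rho,delta vectors from [local_density()] and
#'   [separation_distance()].
#' @param n_clusters number of centers `|C|`.
#' @return integer vector of center indices, in decreasing score order.
#' @export
select_centers <- function(rho, delta, n_clusters) {
  if (n_clusters > length(rho)) stop("n_clusters exceeds the number of genes")
  score <- rho * delta
  order(-score, seq_along(score))[seq_len(n_clusters)]
}

#' Assign genes to centers and aggregate cluster features
#'
#' Each gene joins the nearest center (squared Euclidean distance, ties to
#' the lower center rank); each center is pinned to its own cluster. Row `c`
#' of `G_c` is, by default, the mean of the rows assigned to cluster `c`
#' ("mean" representative); with `representative = "center"` it is the
#' center gene's own row.
#'
#' @param G numeric matrix `L x D_P`.
#' @param centers integer vector of center indices (rank order = cluster id).
#' @param representative `"mean"` or `"center"`.
#' @param rho,delta optional vectors carried into the result.
#' @return list of class `bs_clustering` with elements `density`,
#'   `separation`, `centers`, `assignment` (1-based cluster ids) and `G_c`.
#' @export
assign_and_aggregate <- function(G, centers, representative = c("mean", "center"),
                                 rho = NULL, delta = NULL) {
  representative <- match.arg(representative)
  L <- nrow(G)
  stopifnot(!anyDuplicated(centers), all(centers >= 1), all(centers <= L))
  C <- G[centers, , drop = FALSE]
  # squared distance of every gene to every center
  gg <- rowSums(G * G)
  cc <- rowSums(C * C)
  d2 <- outer(gg, cc, "+") - 2 * tcrossprod(G, C)
  assignment <- max.col(-d2, ties.method = "first")
  assignment[centers] <- seq_along(centers)
  G_c <- if (representative == "mean") {
    rowsum(G, factor(assignment, levels = seq_along(centers))) /
      tabulate(assignment, nbins = length(centers))
  } else {
    G[centers, , drop = FALSE]
  }
  dimnames(G_c) <- NULL
  structure(list(density = rho, separation = delta, centers = as.integer(centers),
                 assignment = assignment, G_c = G_c),
            class = "bs_clustering")
}

#' DPC-KNN clustering of an enriched gene matrix
#'
#' Runs the full pipeline: local densities, separation distances, center
#' selection by `rho * delta`, nearest-center assignment, and cluster
#' aggregation.
#'
#' @param G numeric matrix `L x D_P`.
#' @param k neighbour count for the density estimate.
#' @param n_clusters number of clusters `|C|`.
#' @param representative cluster representative, `"mean"` (default) or
#'   `"center"`.
#' @return a `bs_clustering` result.
#' @export
dpc_knn <- function(G, k = 8, n_clusters = 32, representative = "mean") {
  rho <- local_density(G, k)
  delta <- separation_distance(G, rho)
  centers <- select_centers(rho, delta, n_clusters)
  assign_and_aggregate(G, centers, representative, rho = rho, delta = delta)
}

#' Comparator clusterings with the same result contract
#'
#' Alternative gene-compression clusterings (k-means, DBSCAN) returning the
#' same `bs_clustering` structure as [dpc_knn()], so downstream code is
#' agnostic to the method. For k-means the reported center of a cluster is
#' its member gene closest to the centroid; DBSCAN (implemented here with
#' the classical eps/minPts region query) assigns its noise points to the
#' nearest discovered cluster centroid and ignores `n_clusters`.
#'
#' @param G numeric matrix `L x D_P`.
#' @param method `"kmeans"` or `"dbscan"`.
#' @param n_clusters cluster count (k-means).
#' @param eps,min_pts DBSCAN neighbourhood radius and minimum neighbourhood
#'   size; `eps = NULL` uses the median distance to the `min_pts`-th
#'   neighbour.
#' @param seed RNG seed for the k-means restarts.
#' @return a `bs_clustering` result (density and separation are `NULL`).
#' @export
comparator_clustering <- function(G, method = c("kmeans", "dbscan"),
                                  n_clusters = 32, eps = NULL, min_pts = 4,
                                  seed = 1L) {
  method <- match.arg(method)
  L <- nrow(G)
  if (method == "kmeans") {
    set.seed(seed)
    km <- stats::kmeans(G, centers = n_clusters, nstart = 5, iter.max = 50)
    assignment <- km$cluster
    centers <- vapply(seq_len(n_clusters), function(c) {
      members <- which(assignment == c)
      d2 <- rowSums((G[members, , drop = FALSE] -
                       matrix(km$centers[c, ], length(members), ncol(G),
                              byrow = TRUE))^2)
      members[which.min(d2)]
    }, integer(1))
    G_c <- unname(km$centers)
    return(structure(list(density = NULL, separation = NULL,
                          centers = centers, assignment = assignment,
                          G_c = G_c), class = "bs_clustering"))
  }
  dm <- as.matrix(stats::dist(G))
  if (is.null(eps)) {
    kth <- apply(dm, 1, function(r) sort(r)[min(min_pts + 1, L)])
    eps <- stats::median(kth)
  }
  labels <- integer(L)  # 0 = unvisited/noise
  cl <- 0L
  for (i in seq_len(L)) {
    if (labels[i] != 0L) next
    nb <- which(dm[i, ] <= eps)
    if (length(nb) < min_pts) next  # provisional noise
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb, i)
    while (length(queue) > 0L) {
      j <- queue[1]; queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        nb_j <- which(dm[j, ] <= eps)
        if (length(nb_j) >= min_pts) queue <- union(queue, nb_j[labels[nb_j] == 0L])
      }
    }
  }
  if (cl == 0L) {
    stop("DBSCAN found no core points: increase eps (", signif(eps, 4),
         ") or decrease min_pts (", min_pts, ")")
  }
  core <- labels > 0
  cents <- rowsum(G[core, , drop = FALSE],
                  factor(labels[core], levels = seq_len(cl))) /
    tabulate(labels[core], nbins = cl)
  noise <- which(labels == 0L)
  if (length(noise) > 0L) {
    d2n <- outer(rowSums(G[noise, , drop = FALSE]^2), rowSums(cents^2), "+") -
      2 * tcrossprod(G[noise, , drop = FALSE], cents)
    labels[noise] <- max.col(-d2n, ties.method = "first")
  }
  centers <- vapply(seq_len(cl), function(c) {
    members <- which(labels == c)
    d2 <- rowSums((G[members, , drop = FALSE] -
                     matrix(cents[c, ], length(members), ncol(G), byrow = TRUE))^2)
    members[which.min(d2)]
  }, integer(1))
  G_c <- rowsum(G, factor(labels, levels = seq_len(cl))) /
    tabulate(labels, nbins = cl)
  dimnames(G_c) <- NULL
  structure(list(density = NULL, separation = NULL, centers = centers,
                 assignment = labels, G_c = G_c), class = "bs_clustering")
}
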
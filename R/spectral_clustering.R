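# Graph Laplacians, spectral embedding via the random-walk Laplacian, and
# Lloyd's K-means on the embedding.

#' Degree matrix of a similarity graph
#'
#' @param g A `SimilarityGraph`.
#' @return Sparse diagonal matrix with `D[i, i] = sum_j W[i, j]`.
#' @export
degree_matrix <- function(g) {
  Matrix::Diagonal(x = Matrix::rowSums(g$w))
}

#' Graph Laplacian
#'
#' Unnormalized: `L = D - W` (symmetric, zero row sums).  Normalized
#' (random-walk): `L_rw = D^{-1} L`, which requires every vertex degree to
#' be positive; vertices of degree zero either raise an error or, when
#' `degree_floor` is given, have their degree floored.
#'
#' @param g A `SimilarityGraph`.
#' @param normalized Logical.
#' @param degree_floor `NULL` (error on an isolated vertex) or a small
#'   positive number added in place of zero degrees.
#' @return A (sparse) matrix.
#' @export
laplacian <- function(g, normalized = FALSE, degree_floor = NULL) {
  deg <- Matrix::rowSums(g$w)
  l <- Matrix::Diagonal(x = deg) - g$w
  if (!normalized) return(l)
  if (any(deg <= 0)) {
    if (is.null(degree_floor)) {
      stop_si(paste("graph has isolated (zero-degree) vertices; drop them or set",
                    "a degree_floor for epsilon-regularization"),
              "singular_degree")
    }
    deg[deg <= 0] <- degree_floor
  }
  Matrix::Diagonal(x = 1 / deg) %*% l
}

#' Spectral embedding from the random-walk Laplacian
#'
#' Returns the eigenvectors of the `K` smallest eigenvalues of
#' `L_rw = D^{-1}(D - W)`.  For numerical stability the problem is solved
#' in symmetric form: the eigenpairs of `D^{-1/2} L D^{-1/2}` share the
#' eigenvalues of `L_rw`, and its eigenvectors `u` map back via
#' `e = D^{-1/2} u`.  The embedding rows are *not* row-normalized
#' (random-walk formulation, not the Ng-Jordan-Weiss variant).
#'
#' @param g A `SimilarityGraph`.
#' @param K Number of eigenpairs (clusters).
#' @param degree_floor As in [laplacian()].
#' @return List with `embedding` (N x K matrix) and `eigenvalues`
#'   (ascending, length K; the first is ~0 on a connected graph).
#' @export
spectral_embed <- function(g, K, degree_floor = NULL) {
  n <- g$n
  if (K > n) stop_si("K cannot exceed the number of genes", "parameter")
  deg <- Matrix::rowSums(g$w)
  if (any(deg <= 0)) {
    if (is.null(degree_floor)) {
      stop_si(paste("graph has isolated (zero-degree) vertices; drop them or set",
                    "a degree_floor for epsilon-regularization"),
              "singular_degree")
    }
    deg[deg <= 0] <- degree_floor
  }
  dhalf <- 1 / sqrt(deg)
  w <- as.matrix(g$w)
  lsym <- -(dhalf * w) * rep(dhalf, each = n)   # D^-1/2 (-W) D^-1/2
  diag(lsym) <- diag(lsym) + 1                  # + I  (D^-1/2 D D^-1/2)
  es <- eigen(lsym, symmetric = TRUE)
  idx <- seq(n, n - K + 1L)                     # eigen() sorts descending
  lambda <- es$values[idx]
  vec <- es$vectors[, idx, drop = FALSE]
  emb <- vec * dhalf                            # back-transform to L_rw space
  list(embedding = emb, eigenvalues = pmax(lambda, 0))
}

#' Lloyd's K-means with greedy farthest-point seeding
#'
#' Deterministic given `seed`: each restart picks a random first centroid,
#' adds the remaining `K - 1` greedily as the point farthest from its
#' nearest chosen centroid, then iterates assignment / centroid updates
#' until the maximum centroid shift drops below `tol` or `max_iter` is
#' reached.  A cluster that empties is reseeded at the point farthest from
#' its assigned centroid.  The restart with the lowest within-cluster sum
#' of squares wins.
#'
#' @param points N x P numeric matrix.
#' @param K Cluster count (`K <= N`).
#' @param seed Integer RNG seed (caller's RNG state is preserved).
#' @param n_restarts,max_iter,tol Iteration controls.
#' @return List with `assignments` (length N, values in 1..K), `centers`,
#'   and `wcss`.
#' @export
kmeans_lloyd <- function(points, K, seed = 1L, n_restarts = 10L,
                         max_iter = 300L, tol = 1e-6) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (K > n) stop_si("K cannot exceed the number of points", "parameter")
  if (K == n) {
    return(list(assignments = seq_len(n), centers = points, wcss = 0))
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      centers <- points[seed_farthest(points, K, sample.int(n, 1L)), , drop = FALSE]
      prev_assign <- NULL
      for (it in seq_len(max_iter)) {
        dc <- point_center_dist2(points, centers)
        assign <- max.col(-dc, ties.method = "first")
        for (kk in which(tabulate(assign, K) == 0L)) {
          far <- which.max(dc[cbind(seq_len(n), assign)])
          centers[kk, ] <- points[far, ]
          assign[far] <- kk
        }
        newc <- centers
        for (kk in seq_len(K)) {
          newc[kk, ] <- colMeans(points[assign == kk, , drop = FALSE])
        }
        shift <- sqrt(max(rowSums((newc - centers)^2)))
        centers <- newc
        if (shift < tol) break
        prev_assign <- assign
      }
      dc <- point_center_dist2(points, centers)
      assign <- max.col(-dc, ties.method = "first")
      wcss <- sum(dc[cbind(seq_len(n), assign)])
      if (is.null(best) || wcss < best$wcss - 1e-12) {
        best <- list(assignments = assign, centers = centers, wcss = wcss)
      }
    }
  })
  best
}

# squared Euclidean distances between N points and K centers -> N x K
point_center_dist2 <- function(points, centers) {
  cross <- tcrossprod(points, centers)
  d2 <- outer(rowSums(points^2), rowSums(centers^2), "+") - 2 * cross
  pmax(d2, 0)
}

# greedy farthest-point seeding: start from `first`, repeatedly add the
# point with the largest distance to its nearest chosen seed
seed_farthest <- function(points, K, first) {
  chosen <- first
  mind2 <- point_center_dist2(points, points[first, , drop = FALSE])[, 1L]
  while (length(chosen) < K) {
    nxt <- which.max(mind2)
    chosen <- c(chosen, nxt)
    mind2 <- pmin(mind2, point_center_dist2(points, points[nxt, , drop = FALSE])[, 1L])
  }
  chosen
}

# run code with a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Eigengap heuristic for the cluster count
#'
#' Chooses `K = argmax_i (lambda[i+1] - lambda[i])` over candidates
#' `i in 2..k_max`; ties resolve to the smallest candidate.
#'
#' @param eigenvalues Ascending eigenvalues (length >= 3).
#' @param k_max Largest candidate K (capped at `length(eigenvalues) - 1`).
#' @return Suggested integer K.
#' @export
choose_k <- function(eigenvalues, k_max = length(eigenvalues) - 1L) {
  ne <- length(eigenvalues)
  if (ne < 3L) stop_si("need at least 3 eigenvalues", "parameter")
  cand <- 2:min(k_max, ne - 1L)
  gaps <- eigenvalues[cand + 1L] - eigenvalues[cand]
  cand[which.max(gaps)]
}

#' Spectral clustering of genes
#'
#' The full pipeline: similarity graph, random-walk Laplacian embedding,
#' K-means.  Incomplete genes participate through pairwise-complete
#' distances, so every gene receives a cluster label.
#'
#' @param m An [expression_matrix()].
#' @param h Availability mask.
#' @param gcfg A [graph_config()].
#' @param K Cluster count, or `"auto"` for the eigengap heuristic with
#'   `k_max` candidates.
#' @param seed Integer seed for the K-means restarts.
#' @param k_max Candidate ceiling when `K = "auto"`.
#' @param degree_floor As in [laplacian()].
#' @param ... Passed on to [kmeans_lloyd()].
#' @return A `ClusterModel`: list with `K`, `eigenvalues`, `embedding`,
#'   `assignments`, `clusters` (list of member index vectors), `seed`, and
#'   the `graph`.
#' @export
spectral_cluster <- function(m, h = availability_mask(m),
                             gcfg = graph_config(), K = "auto", seed = 1L,
                             k_max = 10L, degree_floor = NULL, ...) {
  g <- build_graph(m, h, gcfg)
  auto <- identical(K, "auto")
  n_eig <- if (auto) min(k_max + 1L, g$n) else as.integer(K)
  if (!auto && (n_eig < 2L || n_eig > g$n)) {
    stop_si("K must satisfy 2 <= K <= N", "parameter")
  }
  se <- spectral_embed(g, n_eig, degree_floor = degree_floor)
  if (auto) {
    K <- choose_k(se$eigenvalues, k_max = k_max)
    se$embedding <- se$embedding[, seq_len(K), drop = FALSE]
    se$eigenvalues <- se$eigenvalues[seq_len(K)]
  } else {
    K <- n_eig
  }
  km <- kmeans_lloyd(se$embedding, K, seed = seed, ...)
  structure(
    list(K = K, eigenvalues = se$eigenvalues, embedding = se$embedding,
         assignments = km$assignments,
         clusters = split(seq_len(g$n), km$assignments),
         seed = seed, graph = g),
    class = "ClusterModel"
  )
}

#' @export
print.ClusterModel <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("ClusterModel: K=%d clusters over %d genes (sizes: %s)\n",
              x$K, length(x$assignments), paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement; 1 means identical up to relabeling, ~0 is
#' the expectation under independent random labelings.
#'
#' @param a,b Label vectors of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
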
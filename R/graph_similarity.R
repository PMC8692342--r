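# Pairwise-complete distances, Gaussian kernel, and similarity-graph
# construction (full / kNN normal / kNN mutual / epsilon-neighbourhood).

#' Graph construction configuration
#'
#' @param mode One of `"full"`, `"knn_normal"`, `"knn_mutual"`, `"epsilon"`.
#' @param sigma Gaussian kernel bandwidth (> 0), or `"auto"` for the median
#'   heuristic ([auto_sigma()]).
#' @param k_graph Neighbour count for the kNN graph modes.  Distinct from
#'   both the cluster count K and the imputation neighbour count k'.
#' @param epsilon Distance threshold for the epsilon-neighbourhood mode.
#' @return A `GraphConfig` list.
#' @export
graph_config <- function(mode = c("knn_normal", "knn_mutual", "full", "epsilon"),
                         sigma = "auto", k_graph = 20L, epsilon = NULL) {
  mode <- match.arg(mode)
  if (!identical(sigma, "auto")) {
    if (!is.numeric(sigma) || sigma <= 0) {
      stop_si("sigma must be a positive number or 'auto'", "parameter")
    }
  }
  if (mode %in% c("knn_normal", "knn_mutual")) {
    if (!is.numeric(k_graph) || k_graph < 1) {
      stop_si("k_graph must be a positive integer", "parameter")
    }
  }
  if (mode == "epsilon") {
    if (is.null(epsilon) || !is.numeric(epsilon) || epsilon <= 0) {
      stop_si("epsilon mode needs a positive epsilon", "parameter")
    }
  }
  structure(list(mode = mode, sigma = sigma,
                 k_graph = as.integer(k_graph), epsilon = epsilon),
            class = "GraphConfig")
}

#' Distance between two gene rows under missing data
#'
#' Euclidean distance over the co-observed samples, rescaled by
#' `sqrt(M / m_obs)` where `m_obs` is the number of co-observed samples, so
#' that distances computed from different overlap sizes stay comparable
#' (the rescaling is unbiased for the full-data squared distance under
#' MCAR).  Categorical samples contribute 0 when equal and 1 when
#' different, before rescaling.
#'
#' @param a,b Numeric vectors of length M (codes for categorical columns);
#'   `NA` marks missing entries.
#' @param attr_kinds Per-column kind, `"numeric"` or `"categorical"`.
#' @return Nonnegative scalar distance.
#' @export
pairwise_distance <- function(a, b, attr_kinds = rep("numeric", length(a))) {
  stopifnot(length(a) == length(b))
  co <- !is.na(a) & !is.na(b)
  m_obs <- sum(co)
  if (m_obs == 0L) {
    stop_si("no co-observed samples between the two genes", "no_overlap")
  }
  num <- co & attr_kinds == "numeric"
  cat <- co & attr_kinds == "categorical"
  ss <- sum((a[num] - b[num])^2) + sum(a[cat] != b[cat])
  sqrt(ss * length(a) / m_obs)
}

#' Gaussian similarity kernel
#'
#' `exp(-d^2 / (2 sigma^2))`; maps distance 0 to similarity 1 and decreases
#' monotonically, with `sigma` controlling the effective neighbourhood
#' size.
#'
#' @param d Nonnegative distance (vectorised).
#' @param sigma Positive bandwidth.
#' @return Similarity in (0, 1].
#' @export
gaussian_similarity <- function(d, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop_si("sigma must be a single positive number", "parameter")
  }
  exp(-d^2 / (2 * sigma^2))
}

#' All-pairs pairwise-complete distance matrix
#'
#' Vectorised version of [pairwise_distance()] over every gene pair; mixed
#' types add one pass per categorical column.  Pairs with zero co-observed
#' samples get `NA`; the diagonal is 0.
#'
#' @param m An [expression_matrix()].
#' @param h Availability mask.
#' @return Dense symmetric N x N distance matrix.
#' @export
pairwise_distances <- function(m, h = availability_mask(m)) {
  x <- m$values
  n <- nrow(x)
  M <- ncol(x)
  hm <- h * 1
  is_cat <- m$attr_kinds == "categorical"
  x0 <- x
  if (any(is_cat)) x0[, is_cat] <- 0
  x0[!h] <- 0
  sq <- x0^2
  cross <- tcrossprod(x0)
  rowsq <- tcrossprod(sq, hm)            # sum_k x_ik^2 h_ik h_jk
  d2 <- rowsq + t(rowsq) - 2 * cross
  if (any(is_cat)) {
    for (j in which(is_cat)) {
      cj <- x[, j]
      hj <- h[, j]
      mism <- outer(cj, cj, "!=")
      mism[!hj, ] <- FALSE
      mism[, !hj] <- FALSE
      d2 <- d2 + mism
    }
  }
  m_obs <- tcrossprod(hm)
  # cancellation round-off: exact duplicates must come out at distance 0
  # so the zero-distance donor shortcut can fire
  d2[d2 < 4 * .Machine$double.eps * max(rowsq, 1)] <- 0
  d <- sqrt(d2 * M / pmax(m_obs, 1))
  d[m_obs == 0] <- NA_real_
  diag(d) <- 0
  d
}

#' Median-heuristic bandwidth
#'
#' The median of all defined (positive-overlap) pairwise gene distances.
#' Degenerate all-identical data returns the floor `sigma_min`.
#'
#' @param m An [expression_matrix()].
#' @param h Availability mask.
#' @param sigma_min Floor returned when the median distance is 0.
#' @return Positive scalar bandwidth.
#' @export
auto_sigma <- function(m, h = availability_mask(m), sigma_min = 1e-8) {
  d <- pairwise_distances(m, h)
  vals <- d[upper.tri(d)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) {
    stop_si("no gene pair has co-observed samples", "no_overlap")
  }
  max(stats::median(vals), sigma_min)
}

#' Build a similarity graph over genes
#'
#' Computes pairwise-complete distances, applies the Gaussian kernel, and
#' retains edges according to the graph mode: `full` keeps every pair with
#' similarity above a sparsity floor; `knn_normal` keeps (i, j) when i is
#' among the `k_graph` nearest neighbours of j *or* vice versa;
#' `knn_mutual` requires both; `epsilon` keeps pairs with distance strictly
#' below `epsilon`.  Ties at the k-th neighbour distance are all kept.
#' Pairs with no co-observed samples are treated as similarity 0.  The
#' result is stored as a sparse symmetric matrix.
#'
#' @param m An [expression_matrix()].
#' @param h Availability mask.
#' @param cfg A [graph_config()].
#' @param drop_below Full-mode sparsity floor: similarities below it are
#'   not stored.
#' @return A `SimilarityGraph`: list with `n`, sparse symmetric weight
#'   matrix `w` (zero diagonal), the `sigma` used, and the `mode`.
#' @export
build_graph <- function(m, h = availability_mask(m), cfg = graph_config(),
                        drop_below = 1e-12) {
  n <- nrow(m$values)
  if (n < 2L) stop_si("need at least two genes", "invalid_input")
  d <- pairwise_distances(m, h)
  sigma <- if (identical(cfg$sigma, "auto")) auto_sigma(m, h) else cfg$sigma
  s <- gaussian_similarity(d, sigma)
  s[is.na(d)] <- 0
  diag(s) <- 0
  keep <- switch(cfg$mode,
    full = s >= drop_below,
    epsilon = !is.na(d) & d < cfg$epsilon,
    knn_normal = ,
    knn_mutual = {
      nb <- knn_adjacency(d, cfg$k_graph)
      if (cfg$mode == "knn_normal") nb | t(nb) else nb & t(nb)
    })
  diag(keep) <- FALSE
  w <- Matrix::Matrix(ifelse(keep, s, 0), sparse = TRUE)
  w <- Matrix::forceSymmetric(w, uplo = "U")
  deg <- Matrix::rowSums(w)
  if (any(deg == 0)) {
    warning(sprintf("%d isolated vertex/vertices in similarity graph",
                    sum(deg == 0)))
  }
  structure(list(n = n, w = w, sigma = sigma, mode = cfg$mode),
            class = "SimilarityGraph")
}

# Directed kNN adjacency: nb[i, j] = TRUE iff j is among the k nearest
# neighbours of i (self and NA-distance pairs excluded); ties at the k-th
# distance are all kept.
knn_adjacency <- function(d, k) {
  n <- nrow(d)
  nb <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    di <- d[i, ]
    di[i] <- NA
    ok <- which(!is.na(di))
    if (length(ok) == 0L) next
    kk <- min(k, length(ok))
    thr <- sort(di[ok], partial = kk)[kk]
    nb[i, ok[di[ok] <= thr]] <- TRUE
  }
  nb
}

#' @export
print.SimilarityGraph <- function(x, ...) {
  ne <- Matrix::nnzero(x$w) / 2
  cat(sprintf("SimilarityGraph: %d vertices, %d edges, mode=%s, sigma=%.4g\n",
              x$n, ne, x$mode, x$sigma))
  invisible(x)
}

#' Export a graph as a three-column edge list
#'
#' @param g A `SimilarityGraph`.
#' @param path Optional TSV output path; when `NULL` the data frame is
#'   returned only.
#' @return Data frame with columns `i`, `j`, `similarity` (i < j).
#' @export
graph_edge_list <- function(g, path = NULL) {
  tw <- methods::as(methods::as(Matrix::triu(g$w), "generalMatrix"), "TsparseMatrix")
  df <- data.frame(i = tw@i + 1L, j = tw@j + 1L, similarity = tw@x)
  df <- df[df$i < df$j, ]
  df <- df[order(df$i, df$j), ]
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
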